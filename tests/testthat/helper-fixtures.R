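# Hand-built fixtures and independent oracles used across the suite.

# A 6-woman toy cohort with known tallies: 2 events, 4 censored.
toy_cohort <- function() {
  visits <- data.frame(
    woman_id = c("a", "a", "a", "b", "b", "c", "d", "e", "f"),
    visit_time = c(0, 2, 4, 0, 2, 0, 0, 0, 2),
    age_at_visit = c(55, 57, 59, 50, 52, 65, 60, 52, 54),
    family_history = c(0, 0, 0, 1, 1, 0, 0, 1, 1),
    bbd_category = c("none", "none", "non_proliferative", "none", "none",
                     "prior_biopsy_unknown", "none", "none", "none"),
    mammo_feature = c("none", "mass", "none", "none", "calcifications",
                      "none", "none", "none", "mass"),
    stringsAsFactors = FALSE)
  visits <- rbind(visits,
                  data.frame(woman_id = "f", visit_time = 0,
                             age_at_visit = 52, family_history = 1,
                             bbd_category = "none",
                             mammo_feature = "none",
                             stringsAsFactors = FALSE))
  outcomes <- data.frame(
    woman_id = c("a", "b", "c", "d", "e", "f"),
    event = c(0, 1, 0, 0, 1, 0),
    end_time = c(6, 3, 2, 2, 0.5, 4),
    stringsAsFactors = FALSE)
  screening_cohort(visits, outcomes)
}

# Write a cohort to temporary CSVs; returns the two paths.
write_cohort_csvs <- function(cohort, dir = tempfile("cohort_csv_")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vp <- file.path(dir, "visits.csv")
  op <- file.path(dir, "outcomes.csv")
  utils::write.csv(cohort$visits, vp, row.names = FALSE)
  utils::write.csv(cohort$outcomes, op, row.names = FALSE)
  list(visits = vp, outcomes = op)
}

# Brute-force log partial likelihood (Efron ties) for a single numeric
# covariate, written as explicit loops over risk sets -- the independent
# oracle for the Newton engine.
brute_loglik_1cov <- function(time, event, z, beta) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    dset <- which(event == 1 & time == t)
    rset <- which(time >= t)
    dsum <- sum(exp(beta * z[dset]))
    rsum <- sum(exp(beta * z[rset]))
    dsize <- length(dset)
    ll <- ll + sum(beta * z[dset])
    for (l in seq_len(dsize) - 1)
      ll <- ll - log(rsum - (l / dsize) * dsum)
  }
  ll
}

# AUC by explicit enumeration of case-control pairs (half credit ties).
brute_auc <- function(case_scores, control_scores) {
  tot <- 0
  for (a in case_scores) for (b in control_scores)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(case_scores) * length(control_scores))
}

# Stacked records for a single binary covariate, one record per woman.
simple_stacked <- function(time, event, z, id = NULL) {
  n <- length(time)
  data.frame(
    woman_id = id %||% sprintf("w%04d", seq_len(n)),
    landmark_time = 0,
    age_at_visit = 59.5,   # centered out of the design
    family_history = z,
    bbd_category = "none",
    mammo_feature = "none",
    residual_time = time,
    event = event,
    stringsAsFactors = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# A fit object with all coefficients pinned at zero, for closed-form
# checks of the baseline-hazard estimator.
null_fit <- function(spec = "family_history") {
  nm <- switch(spec, family_history = "family_history", age = "age")
  structure(list(beta = stats::setNames(0, nm), covariate_spec = spec,
                 naive_cov = matrix(0, 1, 1, dimnames = list(nm, nm)),
                 robust_cov = matrix(0, 1, 1, dimnames = list(nm, nm)),
                 ties = "efron", age_center = 59.5,
                 dropped_terms = character(0), flags = character(0)),
            class = "pc_cox_fit")
}

# Small simulated cohort shared by several files (cached per session).
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(sim_config(n_women = 8000, seed = 7301))
    cache
  }
})
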