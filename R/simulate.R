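# Synthetic screening-cohort generator.
#
# Emulates a population-based biennial mammography screening program for
# women aged 50-69: entry age drawn from the program's age mix, visits
# every 2 years until age 69, non-continuation, or breast cancer; family
# history fixed at entry; benign breast disease (BBD) absorbing and
# ordered; mammographic features following a reversible persistence
# chain stationary at the configured per-visit prevalences; breast-cancer
# events drawn from a piecewise-constant proportional hazard
# lambda0 * exp(beta' Z(s)) with covariates frozen between visits; women
# without an event censored at their last attended mammogram + 2 years.

#' Simulation configuration
#'
#' @param n_women number of women to simulate.
#' @param seed integer RNG seed; the generator is fully reproducible
#'   given the seed.
#' @param entry_age_weights probabilities over entry-age bands 50-54,
#'   55-59, 60-64, 65-69 (age uniform within the band).
#' @param per_round_continuation probability that a woman attends the
#'   next biennial screen; folds death and drop-out together.
#' @param famhist_prev prevalence of first-degree family history, fixed
#'   at entry.
#' @param bbd_baseline_probs probabilities over the four BBD categories
#'   at the first screen (none, prior biopsy unknown, non-proliferative,
#'   proliferative).
#' @param bbd_progression per-round probabilities that a woman with no
#'   BBD acquires each of the three non-none categories; non-none states
#'   are absorbing.
#' @param feature_probs per-visit probabilities over the six mammographic
#'   feature categories.
#' @param feature_persistence probability that a non-none feature is
#'   reported again at the next screen. Features evolve by a reversible
#'   two-state-per-category chain: a non-none feature persists with this
#'   probability and reverts to "none" otherwise, while a woman with no
#'   feature acquires category c with probability
#'   `feature_probs[c] * (1 - persistence) / feature_probs["none"]`, so
#'   the per-visit marginals stay at `feature_probs` for any persistence.
#'   High persistence keeps the landmark model near-correctly specified
#'   (a feature frozen at a landmark still describes the hazard years
#'   later); at 0 the feature is re-drawn independently at each screen.
#' @param true_log_hr named numeric vector of generating log hazard
#'   ratios: `family_history`, `bbd_prior_biopsy_unknown`,
#'   `bbd_non_proliferative`, `bbd_proliferative`, `mammo_mass`,
#'   `mammo_calcifications`, `mammo_asymmetry`,
#'   `mammo_architectural_distortion`, `mammo_multiple`, `age` (per year,
#'   centered at 59.5).
#' @param lambda0 baseline hazard, events per woman-year for the
#'   reference profile (no risk factors, age 59.5).
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_women = 500, seed = 1)
#' sim <- simulate_cohort(cfg)
#' sim
#' @export
sim_config <- function(n_women = 10000,
                       seed = 1L,
                       entry_age_weights = c(`50-54` = 0.5297,
                                             `55-59` = 0.2146,
                                             `60-64` = 0.1901,
                                             `65-69` = 0.0656),
                       per_round_continuation = 0.81,
                       famhist_prev = 0.1386,
                       bbd_baseline_probs = c(none = 0.7464,
                                              prior_biopsy_unknown = 0.2172,
                                              non_proliferative = 0.0320,
                                              proliferative = 0.0045),
                       bbd_progression = c(prior_biopsy_unknown = 0.008,
                                           non_proliferative = 0.004,
                                           proliferative = 0.0008),
                       feature_probs = c(none = 0.7199, mass = 0.1812,
                                         calcifications = 0.0271,
                                         asymmetry = 0.0281,
                                         architectural_distortion = 0.0104,
                                         multiple = 0.0333),
                       feature_persistence = 0.95,
                       true_log_hr = default_true_log_hr(),
                       lambda0 = NULL) {
  cfg <- list(n_women = n_women, seed = seed,
              entry_age_weights = entry_age_weights / sum(entry_age_weights),
              per_round_continuation = per_round_continuation,
              famhist_prev = famhist_prev,
              bbd_baseline_probs = bbd_baseline_probs,
              bbd_progression = bbd_progression,
              feature_probs = feature_probs,
              feature_persistence = feature_persistence,
              true_log_hr = true_log_hr,
              lambda0 = lambda0)
  if (n_women < 1) sr_stop("n_women must be >= 1", "simulate", "ECONFIG")
  for (nm in c("entry_age_weights", "bbd_baseline_probs", "feature_probs")) {
    p <- cfg[[nm]]
    # printed percentages can be off by rounding; renormalize within 1e-3
    if (any(p < 0) || abs(sum(p) - 1) > 1e-3)
      sr_stop(paste(nm, "must be nonnegative and sum to 1"),
              "simulate", "ECONFIG")
    cfg[[nm]] <- p / sum(p)
  }
  if (length(cfg$bbd_baseline_probs) != 4 || length(cfg$feature_probs) != 6)
    sr_stop("wrong number of category probabilities", "simulate", "ECONFIG")
  if (per_round_continuation < 0 || per_round_continuation > 1 ||
      famhist_prev < 0 || famhist_prev > 1 ||
      feature_persistence < 0 || feature_persistence > 1 ||
      any(bbd_progression < 0) || sum(bbd_progression) > 1)
    sr_stop("probabilities must lie in [0, 1]", "simulate", "ECONFIG")
  need <- c("family_history", "bbd_prior_biopsy_unknown",
            "bbd_non_proliferative", "bbd_proliferative", "mammo_mass",
            "mammo_calcifications", "mammo_asymmetry",
            "mammo_architectural_distortion", "mammo_multiple", "age")
  miss <- setdiff(need, names(cfg$true_log_hr))
  if (length(miss))
    sr_stop(paste("true_log_hr missing term(s):",
                  paste(miss, collapse = ", ")), "simulate", "ECONFIG")
  if (is.null(cfg$lambda0))
    cfg$lambda0 <- calibrate_baseline(cfg, target_rate = 2.183e-3)
  if (cfg$lambda0 < 0)
    sr_stop("lambda0 must be >= 0", "simulate", "ECONFIG")
  structure(cfg, class = "sim_config")
}

#' Generating hazard ratios of the default configuration
#'
#' Point estimates of the age-adjusted hazard ratios for the three
#' screening risk factors (family history 1.67; BBD 1.36/1.41/3.02;
#' mammographic features 1.32/2.52/1.66/2.07/1.86), with a zero age
#' effect so parameter-recovery experiments have a known truth.
#' @return named numeric vector of log hazard ratios.
#' @export
default_true_log_hr <- function() {
  log(c(family_history = 1.67,
        bbd_prior_biopsy_unknown = 1.36,
        bbd_non_proliferative = 1.41,
        bbd_proliferative = 3.02,
        mammo_mass = 1.32,
        mammo_calcifications = 2.52,
        mammo_asymmetry = 1.66,
        mammo_architectural_distortion = 2.07,
        mammo_multiple = 1.86,
        age = exp(0)))
}

#' Default screening-program configuration
#'
#' Covariate prevalences follow the emulated program's non-case column
#' (family history 13.86%, BBD 74.64/21.72/3.20/0.45%, features
#' 71.99/18.12/2.71/2.81/1.04/3.33%, entry ages 52.97/21.46/19.01/6.56%),
#' generating hazard ratios are the published point estimates, the
#' baseline hazard is calibrated so the marginal incidence is 2.183
#' events per 1,000 woman-years, and the continuation probability is
#' tuned so mean follow-up is about 7.5 years.
#'
#' @param n_women,seed passed to [sim_config()].
#' @return A `sim_config`.
#' @export
default_sim_config <- function(n_women = 10000, seed = 1L) {
  sim_config(n_women = n_women, seed = seed)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  n_women=%d seed=%d lambda0=%.6g/woman-year\n",
              x$n_women, as.integer(x$seed), x$lambda0))
  cat(sprintf("  continuation=%.2f famhist=%.3f persistence=%.2f\n",
              x$per_round_continuation, x$famhist_prev,
              x$feature_persistence))
  cat("  true HRs:",
      paste(sprintf("%s=%.2f", names(x$true_log_hr),
                    exp(x$true_log_hr)), collapse = " "), "\n")
  invisible(x)
}

# Mean of exp(beta'Z) over the configured covariate distribution.
# Features use their stationary distribution under the
# persistence-with-redraw chain; BBD uses the baseline mix (progression
# is a small per-round perturbation); the age term uses the entry-age
# mix shifted by half the nominal follow-up.
expected_relative_hazard <- function(config) {
  b <- config$true_log_hr
  fam <- (1 - config$famhist_prev) +
    config$famhist_prev * exp(b["family_history"])
  bbd_hr <- c(1, exp(b[c("bbd_prior_biopsy_unknown",
                         "bbd_non_proliferative", "bbd_proliferative")]))
  bbd <- sum(config$bbd_baseline_probs * bbd_hr)
  # the persistence chain is stationary at feature_probs by construction
  feat_hr <- c(1, exp(b[c("mammo_mass", "mammo_calcifications",
                          "mammo_asymmetry", "mammo_architectural_distortion",
                          "mammo_multiple")]))
  feat <- sum(config$feature_probs * feat_hr)
  if (abs(b["age"]) < 1e-12) {
    agem <- 1
  } else {
    mids <- c(52.5, 57.5, 62.5, 67.5) + 3.75 / 2
    agem <- sum(config$entry_age_weights *
                  exp(b["age"] * (mids - AGE_CENTER)))
  }
  unname(fam * bbd * feat * agem)
}

#' Calibrate the baseline hazard to a target marginal incidence
#'
#' Finds `lambda0` such that the expected marginal event rate (events per
#' woman-year of follow-up) under the configured covariate mixture equals
#' `target_rate`. The analytic method divides the target by the mean
#' relative hazard over the (stationary) covariate distribution; the
#' simulation method bisects on short simulated cohorts.
#'
#' @param config a `sim_config` (its `lambda0` is ignored).
#' @param target_rate events per woman-year, > 0.
#' @param method `"analytic"` (default) or `"simulate"`.
#' @param n_sim,seed cohort size and seed for the simulation method.
#' @return the calibrated `lambda0`.
#' @export
calibrate_baseline <- function(config, target_rate,
                               method = c("analytic", "simulate"),
                               n_sim = 20000, seed = 1L) {
  method <- match.arg(method)
  if (target_rate <= 0)
    sr_stop("target_rate must be > 0", "simulate", "ECALIB")
  mult <- expected_relative_hazard(config)
  lam <- target_rate / mult
  if (!is.finite(lam) || lam <= 0)
    sr_stop("target rate unattainable under this configuration",
            "simulate", "ECALIB")
  if (method == "analytic") return(lam)
  rate_at <- function(l0) {
    cfg <- unclass(config)
    cfg$lambda0 <- l0; cfg$n_women <- n_sim; cfg$seed <- seed
    sim <- simulate_cohort(do.call(sim_config, cfg))
    sum(sim$cohort$outcomes$event) / sum(sim$cohort$outcomes$end_time)
  }
  lo <- lam / 3; hi <- lam * 3
  for (i in 1:25) {
    mid <- (lo + hi) / 2
    if (rate_at(mid) < target_rate) lo <- mid else hi <- mid
    if ((hi - lo) / lam < 0.005) break
  }
  (lo + hi) / 2
}

#' Simulate a screening cohort
#'
#' @param config a `sim_config`.
#' @return A list of class `simulated_cohort` with elements `cohort` (a
#'   [screening_cohort()]) and `truth` (the hidden per-woman hazard path:
#'   one row per attended round with the true hazard on the following
#'   2-year interval; never exported with the cohort CSVs).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_women
    b <- config$true_log_hr
    band <- sample.int(4L, n, replace = TRUE,
                       prob = config$entry_age_weights)
    entry_age <- c(50, 55, 60, 65)[band] + stats::runif(n) * 5
    # everyone attends her entry screen; later invitations stop at 69
    vmax <- pmax(1L, floor((69 - entry_age) / 2) + 1)
    q <- config$per_round_continuation
    v_att <- if (q >= 1) vmax
             else pmin(vmax, 1L + stats::rgeom(n, prob = 1 - q))
    maxv <- max(v_att)
    fam <- stats::rbinom(n, 1L, config$famhist_prev)

    bbd <- matrix(0L, n, maxv)
    feat <- matrix(0L, n, maxv)
    bbd[, 1] <- sample.int(4L, n, replace = TRUE,
                           prob = config$bbd_baseline_probs)
    feat[, 1] <- sample.int(6L, n, replace = TRUE,
                            prob = config$feature_probs)
    prog <- config$bbd_progression
    cp <- cumsum(prog)
    if (maxv > 1) for (r in 2:maxv) {
      prev <- bbd[, r - 1]
      u <- stats::runif(n)
      nb <- prev
      none <- prev == 1L
      nb[none & u < cp[1]] <- 2L
      nb[none & u >= cp[1] & u < cp[2]] <- 3L
      nb[none & u >= cp[2] & u < cp[3]] <- 4L
      bbd[, r] <- nb
      # reversible feature chain, stationary at feature_probs
      rho <- config$feature_persistence
      fpn <- config$feature_probs[1]
      acq <- config$feature_probs[-1] * (1 - rho) / fpn
      u2 <- stats::runif(n)
      prevf <- feat[, r - 1]
      nf <- prevf
      hasf <- prevf != 1L
      nf[hasf & u2 >= rho] <- 1L
      ca <- cumsum(acq)
      nonef <- !hasf
      for (c in 5:1)
        nf[nonef & u2 < ca[c]] <- c + 1L
      feat[, r] <- nf
    }

    bbd_lhr <- c(0, b[["bbd_prior_biopsy_unknown"]],
                 b[["bbd_non_proliferative"]], b[["bbd_proliferative"]])
    feat_lhr <- c(0, b[["mammo_mass"]], b[["mammo_calcifications"]],
                  b[["mammo_asymmetry"]],
                  b[["mammo_architectural_distortion"]],
                  b[["mammo_multiple"]])

    # hazard on each attended inter-visit interval (all of length 2y);
    # event time by inversion of the piecewise-constant cumulative hazard
    E <- stats::rexp(n)
    cumh <- numeric(n)
    ev_round <- rep(NA_integer_, n)
    ev_time <- rep(NA_real_, n)
    lam_mat <- matrix(NA_real_, n, maxv)
    for (r in 1:maxv) {
      act <- r <= v_att
      age_r <- entry_age + 2 * (r - 1)
      lam <- config$lambda0 *
        exp(fam * b[["family_history"]] + bbd_lhr[bbd[, r]] +
              feat_lhr[feat[, r]] + b[["age"]] * (age_r - AGE_CENTER))
      lam[!act] <- NA_real_
      lam_mat[, r] <- lam
      open <- act & is.na(ev_round)
      newh <- cumh + 2 * lam
      hit <- open & newh >= E & lam > 0
      if (any(hit)) {
        ev_round[hit] <- r
        ev_time[hit] <- 2 * (r - 1) + (E[hit] - cumh[hit]) / lam[hit]
      }
      cumh[open] <- newh[open]
    }

    has_event <- !is.na(ev_round)
    end_time <- ifelse(has_event, ev_time, 2 * v_att)
    # visits attended strictly before the event (or all, if censored)
    n_vis <- ifelse(has_event, ev_round, v_att)

    wid <- sprintf("w%06d", seq_len(n))
    rows <- rep(seq_len(n), n_vis)
    rnum <- sequence(n_vis)
    visits <- data.frame(
      woman_id = wid[rows],
      visit_time = 2 * (rnum - 1),
      age_at_visit = entry_age[rows] + 2 * (rnum - 1),
      family_history = fam[rows],
      bbd_category = BBD_LEVELS[bbd[cbind(rows, rnum)]],
      mammo_feature = FEATURE_LEVELS[feat[cbind(rows, rnum)]],
      stringsAsFactors = FALSE)
    outcomes <- data.frame(
      woman_id = wid,
      event = as.integer(has_event),
      end_time = end_time,
      stringsAsFactors = FALSE)
    truth <- data.frame(
      woman_id = wid[rows],
      interval_start = 2 * (rnum - 1),
      hazard = lam_mat[cbind(rows, rnum)],
      stringsAsFactors = FALSE)

    structure(list(cohort = screening_cohort(visits, outcomes),
                   truth = truth, config = config),
              class = "simulated_cohort")
  })
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("<simulated_cohort>\n")
  o <- x$cohort$outcomes
  cat(sprintf("  %d women, %d events, mean follow-up %.2f y, rate %.3g/1000 wy\n",
              nrow(o), sum(o$event), mean(o$end_time),
              1000 * sum(o$event) / sum(o$end_time)))
  invisible(x)
}

#' Write a simulated cohort to CSV files
#'
#' Emits `visits.csv` and `outcomes.csv` in the schema read by
#' [load_cohort()]; the hidden truth is written only if `truth = TRUE`.
#'
#' @param sim a `simulated_cohort`.
#' @param dir output directory (created if needed).
#' @param truth also write `truth.csv` for oracle checks.
#' @return the directory, invisibly.
#' @export
write_sim_cohort <- function(sim, dir, truth = FALSE) {
  stopifnot(inherits(sim, "simulated_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$cohort$visits, file.path(dir, "visits.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$cohort$outcomes, file.path(dir, "outcomes.csv"),
                   row.names = FALSE)
  if (truth)
    utils::write.csv(sim$truth, file.path(dir, "truth.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file whose keys are [sim_config()] arguments.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path))
    sr_stop(paste("config file not found:", path), "simulate", "ENOENT")
  raw <- yaml::read_yaml(path)
  for (nm in c("entry_age_weights", "bbd_baseline_probs",
               "bbd_progression", "feature_probs", "true_log_hr"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  do.call(sim_config, raw)
}
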