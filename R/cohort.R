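# Cohort ingestion and restructuring.
#
# A screening cohort is two tables: one row per woman-visit (the covariate
# values recorded at that screen) and one outcome row per woman (breast
# cancer event indicator and event/censor time, both on the time axis that
# starts at her first mammogram). The partly conditional model consumes a
# stacked form: one record per retained visit, with covariates frozen at
# the visit and the residual follow-up time from that landmark.

#' Construct a screening cohort object
#'
#' Validates a visits table and an outcomes table against the schema used
#' throughout the package and bundles them as a `screening_cohort`.
#'
#' @param visits data.frame with columns `woman_id`, `visit_time` (years
#'   since the woman's first mammogram), `age_at_visit`, `family_history`
#'   (0/1, `NA` allowed until exclusions), `bbd_category` (one of
#'   `"none"`, `"prior_biopsy_unknown"`, `"non_proliferative"`,
#'   `"proliferative"`; `NA` allowed until exclusions), `mammo_feature`
#'   (one of `"none"`, `"mass"`, `"calcifications"`, `"asymmetry"`,
#'   `"architectural_distortion"`, `"multiple"`; blanks are schema
#'   errors).
#' @param outcomes data.frame with columns `woman_id`, `event` (0/1;
#'   invasive cancer and DCIS both count), `end_time` (event time if
#'   `event == 1`, else censor time = last mammogram + 2 years).
#' @param exclusion_log optional named numeric vector of per-rule
#'   exclusion counts (filled by [apply_exclusions()]).
#' @return An object of class `screening_cohort`: a list with elements
#'   `visits`, `outcomes`, `exclusion_log`.
#' @seealso [load_cohort()], [apply_exclusions()], [build_stacked()]
#' @export
screening_cohort <- function(visits, outcomes, exclusion_log = NULL) {
  visits <- as.data.frame(visits)
  outcomes <- as.data.frame(outcomes)
  need_v <- c("woman_id", "visit_time", "age_at_visit", "family_history",
              "bbd_category", "mammo_feature")
  need_o <- c("woman_id", "event", "end_time")
  miss <- setdiff(need_v, names(visits))
  if (length(miss))
    sr_stop(paste("visits table missing column(s):",
                  paste(miss, collapse = ", ")), "load", "ESCHEMA")
  miss <- setdiff(need_o, names(outcomes))
  if (length(miss))
    sr_stop(paste("outcomes table missing column(s):",
                  paste(miss, collapse = ", ")), "load", "ESCHEMA")

  visits$woman_id <- as.character(visits$woman_id)
  outcomes$woman_id <- as.character(outcomes$woman_id)

  bad <- which(!is.na(visits$bbd_category) &
                 !(visits$bbd_category %in% BBD_LEVELS))
  if (length(bad))
    sr_stop(sprintf("unknown bbd_category %s at visits row %d",
                    dQuote(visits$bbd_category[bad[1]]), bad[1]),
            "load", "EENUM")
  bad <- which(is.na(visits$mammo_feature) |
                 !(visits$mammo_feature %in% FEATURE_LEVELS))
  if (length(bad))
    sr_stop(sprintf(
      "mammo_feature %s at visits row %d is not a model category (blank cells are data defects, not a category)",
      dQuote(as.character(visits$mammo_feature[bad[1]])), bad[1]),
      "load", "EENUM")
  bad <- which(!is.na(visits$family_history) &
                 !(visits$family_history %in% c(0, 1)))
  if (length(bad))
    sr_stop(sprintf("family_history must be 0/1 (visits row %d)", bad[1]),
            "load", "EENUM")
  if (any(!(outcomes$event %in% c(0, 1))))
    sr_stop("event must be 0/1", "load", "EENUM")

  if (anyDuplicated(outcomes$woman_id))
    sr_stop("more than one outcome row for a woman", "load", "EDUP")
  if (anyDuplicated(visits[c("woman_id", "visit_time")])) {
    i <- anyDuplicated(visits[c("woman_id", "visit_time")])
    sr_stop(sprintf("duplicate (woman_id, visit_time) at visits row %d: one interpretation per screen", i),
            "load", "EDUP")
  }
  orphan <- setdiff(visits$woman_id, outcomes$woman_id)
  if (length(orphan))
    sr_stop(sprintf("visit without outcome row (woman_id %s)",
                    dQuote(orphan[1])), "load", "ELINK")

  # order within woman and check monotonicity
  visits <- visits[order(visits$woman_id, visits$visit_time), ,
                   drop = FALSE]
  rownames(visits) <- NULL
  if (nrow(visits) > 1) {
    same <- visits$woman_id[-1] == visits$woman_id[-nrow(visits)]
    bad <- which(same & diff(visits$age_at_visit) <= 0)
    if (length(bad))
      sr_stop(sprintf("age_at_visit not strictly increasing for woman %s",
                      dQuote(visits$woman_id[bad[1]])), "load", "EORDER")
  }
  et <- outcomes$end_time[match(visits$woman_id, outcomes$woman_id)]
  bad <- which(visits$visit_time > et)
  if (length(bad))
    sr_stop(sprintf("visit at t=%g after end_time=%g for woman %s",
                    visits$visit_time[bad[1]], et[bad[1]],
                    dQuote(visits$woman_id[bad[1]])), "load", "ELINK")
  first <- tapply(visits$visit_time, visits$woman_id, min)
  keep <- outcomes$woman_id %in% names(first)
  if (any(keep)) {
    f <- first[outcomes$woman_id[keep]]
    if (any(outcomes$end_time[keep] < f))
      sr_stop("end_time before first visit_time", "load", "ELINK")
  }

  log0 <- c(prevalent_first_screen = 0, missing_family_history = 0,
            missing_bbd = 0, missing_both = 0)
  if (!is.null(exclusion_log)) log0[names(exclusion_log)] <- exclusion_log
  structure(list(visits = visits, outcomes = outcomes,
                 exclusion_log = log0),
            class = "screening_cohort")
}

#' Read a screening cohort from CSV files
#'
#' @param visits_path,outcomes_path paths to UTF-8 CSV files with the
#'   column schemas documented in [screening_cohort()].
#' @return A validated `screening_cohort`.
#' @export
load_cohort <- function(visits_path, outcomes_path) {
  for (p in c(visits_path, outcomes_path))
    if (!file.exists(p))
      sr_stop(paste("input file not found:", p), "load", "ENOENT")
  visits <- utils::read.csv(visits_path, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
  outcomes <- utils::read.csv(outcomes_path, stringsAsFactors = FALSE,
                              na.strings = c("NA", ""))
  screening_cohort(visits, outcomes)
}

#' @export
print.screening_cohort <- function(x, ...) {
  cat("<screening_cohort>\n")
  cat(sprintf("  %d women, %d visits, %d events\n",
              nrow(x$outcomes), nrow(x$visits), sum(x$outcomes$event)))
  if (any(x$exclusion_log > 0)) {
    cat("  exclusions applied:\n")
    for (nm in names(x$exclusion_log))
      cat(sprintf("    %-24s %d\n", nm, x$exclusion_log[[nm]]))
  }
  invisible(x)
}

#' Apply the cohort exclusion rules
#'
#' Removes (a) women diagnosed at the first screen (event time equal to
#' the first visit time), and women with missing family history and/or
#' missing benign-breast-disease information at any visit. The
#' `exclusion_log` records one count per rule, with missingness split
#' into family-history-only, BBD-only, and both.
#'
#' @param cohort a `screening_cohort`.
#' @return The filtered `screening_cohort` with an updated
#'   `exclusion_log`.
#' @export
apply_exclusions <- function(cohort) {
  stopifnot(inherits(cohort, "screening_cohort"))
  v <- cohort$visits; o <- cohort$outcomes
  first <- tapply(v$visit_time, v$woman_id, min)
  f <- first[o$woman_id]
  prevalent <- o$woman_id[o$event == 1 & !is.na(f) & o$end_time == f]
  miss_fh_w <- unique(v$woman_id[is.na(v$family_history)])
  miss_bbd_w <- unique(v$woman_id[is.na(v$bbd_category)])
  both <- intersect(miss_fh_w, miss_bbd_w)
  fh_only <- setdiff(miss_fh_w, both)
  bbd_only <- setdiff(miss_bbd_w, both)
  # prevalent rule takes precedence in the counts, as each woman is
  # excluded once
  fh_only <- setdiff(fh_only, prevalent)
  bbd_only <- setdiff(bbd_only, prevalent)
  both <- setdiff(both, prevalent)

  drop <- unique(c(prevalent, fh_only, bbd_only, both))
  log <- cohort$exclusion_log
  log["prevalent_first_screen"] <- log["prevalent_first_screen"] +
    length(prevalent)
  log["missing_family_history"] <- log["missing_family_history"] +
    length(fh_only)
  log["missing_bbd"] <- log["missing_bbd"] + length(bbd_only)
  log["missing_both"] <- log["missing_both"] + length(both)

  v <- v[!(v$woman_id %in% drop), , drop = FALSE]
  o <- o[!(o$woman_id %in% drop), , drop = FALSE]
  rownames(v) <- rownames(o) <- NULL
  if (nrow(o) == 0)
    warning("all women excluded; cohort is empty")
  screening_cohort(v, o, exclusion_log = log)
}

#' Stack a cohort into partly conditional records
#'
#' Produces one record per retained visit: the landmark time `s`, the
#' covariates frozen exactly as recorded at that visit (no carry-forward),
#' the residual follow-up `end_time - s`, and the woman's event
#' indicator. An event woman's event lies inside every record's residual
#' window, so her event flag is copied to all her records. A visit at
#' exactly `end_time` produces no record.
#'
#' @param cohort a `screening_cohort`, normally after
#'   [apply_exclusions()].
#' @return data.frame with columns `woman_id`, `landmark_time`,
#'   `age_at_visit`, `family_history`, `bbd_category`, `mammo_feature`,
#'   `residual_time`, `event`.
#' @export
build_stacked <- function(cohort) {
  stopifnot(inherits(cohort, "screening_cohort"))
  v <- cohort$visits; o <- cohort$outcomes
  m <- match(v$woman_id, o$woman_id)
  end_time <- o$end_time[m]
  event <- o$event[m]
  keep <- v$visit_time < end_time
  out <- data.frame(
    woman_id = v$woman_id[keep],
    landmark_time = v$visit_time[keep],
    age_at_visit = v$age_at_visit[keep],
    family_history = v$family_history[keep],
    bbd_category = factor(v$bbd_category[keep], levels = BBD_LEVELS),
    mammo_feature = factor(v$mammo_feature[keep],
                           levels = FEATURE_LEVELS),
    residual_time = end_time[keep] - v$visit_time[keep],
    event = event[keep],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Export stacked records for audit
#'
#' @param stacked data.frame from [build_stacked()].
#' @param path CSV destination.
#' @export
write_stacked <- function(stacked, path) {
  utils::write.csv(stacked, path, row.names = FALSE)
  invisible(path)
}

#' Baseline characteristics table
#'
#' Summarizes the cohort at each woman's first visit, split by event
#' status: counts and percentages per category, mean follow-up per group
#' with a Mann-Whitney U test, and two-proportion z-tests (no continuity
#' correction) per categorical row, Bonferroni-corrected within each
#' factor.
#'
#' @param cohort a `screening_cohort`, normally after
#'   [apply_exclusions()].
#' @return An object of class `cohort_summary`: a data.frame with one row
#'   per category level (columns `variable`, `level`, `n_no_event`,
#'   `pct_no_event`, `n_event`, `pct_event`, `p_value`, `p_adj`), with
#'   attributes `followup` (mean follow-up per group and the Mann-Whitney
#'   p-value) and `n` (group sizes).
#' @export
describe_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "screening_cohort"))
  v <- cohort$visits; o <- cohort$outcomes
  first_idx <- tapply(seq_len(nrow(v)), v$woman_id, function(i)
    i[which.min(v$visit_time[i])])
  base <- v[unlist(first_idx), , drop = FALSE]
  m <- match(base$woman_id, o$woman_id)
  base$event <- o$event[m]
  base$followup <- o$end_time[m] - base$visit_time

  grp <- factor(ifelse(base$event == 1, "event", "no_event"),
                levels = c("no_event", "event"))
  n_grp <- table(grp)
  vars <- list(
    age_band = age_band(base$age_at_visit),
    family_history = factor(ifelse(base$family_history == 1, "yes", "no"),
                            levels = c("no", "yes")),
    bbd_category = factor(base$bbd_category, levels = BBD_LEVELS),
    mammo_feature = factor(base$mammo_feature, levels = FEATURE_LEVELS)
  )
  rows <- list()
  for (vn in names(vars)) {
    f <- vars[[vn]]
    tab <- table(f, grp)
    k <- nlevels(f)
    for (lv in levels(f)) {
      n0 <- tab[lv, "no_event"]; n1 <- tab[lv, "event"]
      if (all(n_grp > 0)) {
        # two-proportion z-test on membership of this level
        p <- tryCatch(
          stats::prop.test(c(n0, n1), as.vector(n_grp),
                           correct = FALSE)$p.value,
          warning = function(w) suppressWarnings(
            stats::prop.test(c(n0, n1), as.vector(n_grp),
                             correct = FALSE)$p.value))
      } else p <- NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        variable = vn, level = lv,
        n_no_event = as.integer(n0),
        pct_no_event = if (n_grp["no_event"] > 0)
          100 * n0 / n_grp["no_event"] else 0,
        n_event = as.integer(n1),
        pct_event = if (n_grp["event"] > 0)
          100 * n1 / n_grp["event"] else 0,
        p_value = p,
        p_adj = if (is.na(p)) NA_real_ else min(1, p * k),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(n_grp == 0)) {
    message("a group has zero members; between-group tests skipped")
    fu_p <- NA_real_
  } else {
    fu_p <- stats::wilcox.test(followup ~ grp, data = base)$p.value
  }
  attr(out, "followup") <- data.frame(
    group = levels(grp),
    n = as.vector(n_grp),
    mean_followup = as.vector(tapply(base$followup, grp, mean)),
    stringsAsFactors = FALSE)
  attr(out, "followup_p") <- fu_p
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  fu <- attr(x, "followup")
  cat("Baseline characteristics by event status\n")
  cat(sprintf("  no event: n=%d, mean follow-up %.2f y; event: n=%d, mean follow-up %.2f y (Mann-Whitney p=%.3g)\n",
              fu$n[1], fu$mean_followup[1], fu$n[2],
              if (is.na(fu$mean_followup[2])) NA else fu$mean_followup[2],
              attr(x, "followup_p")))
  print.data.frame(x, digits = 4)
  invisible(x)
}
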