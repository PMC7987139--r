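# Split-sample internal validation: calibration (expected-to-observed
# ratios with standardized-ratio confidence intervals) and
# discrimination (horizon-specific AUC with Hanley-McNeil intervals).
# Both use predictions made from each validation woman's baseline
# (first) mammogram.

#' Split a cohort into estimation and validation subcohorts
#'
#' Woman-level random partition: all visits of a woman land on one side.
#'
#' @param cohort a `screening_cohort`.
#' @param fraction proportion of women in the estimation subcohort
#'   (default 0.6).
#' @param seed integer seed; the split is reproducible given the seed.
#' @return list with elements `estimation` and `validation`, both
#'   `screening_cohort`s, disjoint and exhaustive.
#' @export
split_cohort <- function(cohort, fraction = 0.6, seed = 1L) {
  stopifnot(inherits(cohort, "screening_cohort"))
  if (fraction <= 0 || fraction >= 1)
    sr_stop("fraction must lie in (0, 1)", "split", "ESPEC")
  ids <- cohort$outcomes$woman_id
  n_est <- round(length(ids) * fraction)
  if (n_est == 0 || n_est == length(ids))
    sr_stop("split leaves one side empty", "split", "EEMPTY")
  est_ids <- with_seed(seed, sample(ids, n_est))
  take <- function(keep) {
    screening_cohort(
      cohort$visits[cohort$visits$woman_id %in% keep, , drop = FALSE],
      cohort$outcomes[cohort$outcomes$woman_id %in% keep, , drop = FALSE],
      exclusion_log = cohort$exclusion_log)
  }
  list(estimation = take(est_ids),
       validation = take(setdiff(ids, est_ids)))
}

#' Observed cumulative incidence by Kaplan-Meier
#'
#' Woman-level KM estimate of the cumulative breast-cancer incidence at
#' horizon `tau`, measured from each woman's baseline mammogram, and the
#' count of observed events by `tau`.
#'
#' @param cohort a `screening_cohort` (typically the validation side).
#' @param tau horizon in years.
#' @return list with `incidence` (1 - KM survivor at `tau`), `O`
#'   (observed event count by `tau`), `truncated` (`TRUE` if `tau`
#'   exceeds the last observed time, in which case the value at the last
#'   time is reported).
#' @export
observed_risk_km <- function(cohort, tau) {
  stopifnot(inherits(cohort, "screening_cohort"))
  o <- cohort$outcomes
  if (!nrow(o)) sr_stop("empty subcohort", "validate", "EEMPTY")
  km <- survival::survfit(survival::Surv(o$end_time, o$event) ~ 1)
  truncated <- tau > max(km$time)
  sfun <- stats::stepfun(km$time, c(1, km$surv))
  s <- sfun(min(tau, max(km$time)))
  list(incidence = 1 - s,
       O = sum(o$event == 1 & o$end_time <= tau),
       truncated = truncated)
}

#' Expected-to-observed calibration ratio
#'
#' `E / observed_rate` with a 95% CI in the standardized-ratio
#' (log-normal) form `ratio * exp(+/- 1.96 / sqrt(O))`, treating the
#' observed count as Poisson; the exact-Poisson variant (Byar's
#' approximation to the chi-square tail) is available behind `ci`.
#'
#' @param E expected rate: mean model-predicted risk at the horizon.
#' @param observed_rate observed KM cumulative incidence at the horizon.
#' @param O observed event count.
#' @param tau,subgroup labels carried into the result.
#' @param ci `"lognormal"` (default) or `"exact"`.
#' @return one-row data.frame of class `calibration_result`: `horizon`,
#'   `subgroup`, `O`, `observed_rate`, `E`, `eo_ratio`, `ci_low`,
#'   `ci_high`. With `O = 0` the ratio is `NA` and only a one-sided
#'   upper bound on the Poisson mean is reflected in `ci_high`.
#' @examples
#' eo_ratio(E = 0.99, observed_rate = 1, O = 188)  # CI 0.86-1.14
#' @export
eo_ratio <- function(E, observed_rate, O, tau = NA_real_,
                     subgroup = "overall",
                     ci = c("lognormal", "exact")) {
  ci <- match.arg(ci)
  if (O < 0) sr_stop("O must be >= 0", "validate", "ESPEC")
  if (O == 0 || observed_rate <= 0) {
    if (O > 0)
      sr_stop("O > 0 requires observed_rate > 0", "validate", "ESPEC")
    # with zero observed events the ratio is undefined; E/O has a
    # one-sided lower bound from the Poisson upper bound on O
    out <- data.frame(horizon = tau, subgroup = subgroup, O = 0L,
                      observed_rate = observed_rate, E = E,
                      eo_ratio = NA_real_,
                      ci_low = NA_real_, ci_high = Inf,
                      stringsAsFactors = FALSE)
    class(out) <- c("calibration_result", "data.frame")
    return(out)
  }
  ratio <- E / observed_rate
  if (ci == "lognormal") {
    lo <- ratio * exp(-1.96 / sqrt(O))
    hi <- ratio * exp(1.96 / sqrt(O))
  } else {
    # exact-Poisson bounds on O scaled into the ratio
    o_lo <- stats::qchisq(0.025, 2 * O) / 2
    o_hi <- stats::qchisq(0.975, 2 * (O + 1)) / 2
    lo <- ratio * O / o_hi
    hi <- ratio * O / o_lo
  }
  out <- data.frame(horizon = tau, subgroup = subgroup, O = as.integer(O),
                    observed_rate = observed_rate, E = E,
                    eo_ratio = ratio, ci_low = lo, ci_high = hi,
                    stringsAsFactors = FALSE)
  class(out) <- c("calibration_result", "data.frame")
  out
}

#' Horizon-specific AUC with Hanley-McNeil confidence interval
#'
#' Cases are women with an event by `tau`; controls are women followed
#' event-free for at least `tau` years; women censored event-free before
#' `tau` are excluded. The AUC is the concordance over all case-control
#' score pairs with half credit for ties (computed from ranks), and the
#' CI uses the Hanley-McNeil standard error with
#' `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`, clipped to `[0, 1]`.
#'
#' @param scores per-woman risk score (any strictly monotone transform
#'   of predicted risk gives the same AUC).
#' @param outcomes data.frame with `event` and `end_time`, aligned with
#'   `scores`.
#' @param tau horizon in years.
#' @return one-row data.frame of class `discrimination_result`:
#'   `horizon`, `auc`, `ci_low`, `ci_high`, `n_cases`, `n_controls`,
#'   `note`.
#' @examples
#' out <- data.frame(event = c(1, 1, 0, 0, 0),
#'                   end_time = c(1, 2, 9, 9, 9))
#' auc_at_horizon(c(0.9, 0.7, 0.8, 0.1, 0.2), out, tau = 5)  # 5/6
#' @export
auc_at_horizon <- function(scores, outcomes, tau) {
  stopifnot(length(scores) == nrow(outcomes))
  is_case <- outcomes$event == 1 & outcomes$end_time <= tau
  is_ctrl <- outcomes$end_time >= tau & !is_case
  n1 <- sum(is_case); n0 <- sum(is_ctrl)
  if (n1 == 0 || n0 == 0) {
    out <- data.frame(horizon = tau, auc = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, n_cases = n1, n_controls = n0,
                      note = "no eligible cases or controls",
                      stringsAsFactors = FALSE)
    class(out) <- c("discrimination_result", "data.frame")
    return(out)
  }
  s <- scores[is_case | is_ctrl]
  cs <- is_case[is_case | is_ctrl]
  r <- rank(s)                      # midranks give ties half credit
  A <- (sum(r[cs]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  Q1 <- A / (2 - A)
  Q2 <- 2 * A^2 / (1 + A)
  se <- sqrt((A * (1 - A) + (n1 - 1) * (Q1 - A^2) +
                (n0 - 1) * (Q2 - A^2)) / (n1 * n0))
  out <- data.frame(horizon = tau, auc = A,
                    ci_low = max(0, A - 1.96 * se),
                    ci_high = min(1, A + 1.96 * se),
                    n_cases = n1, n_controls = n0, note = "",
                    stringsAsFactors = FALSE)
  class(out) <- c("discrimination_result", "data.frame")
  out
}

# Baseline (first-visit) profile of every woman in a cohort. Visits are
# kept sorted by (woman_id, visit_time) on construction, so the first
# non-duplicated row per woman is her baseline mammogram.
baseline_profiles <- function(cohort) {
  v <- cohort$visits
  base <- v[!duplicated(v$woman_id), , drop = FALSE]
  base <- base[match(cohort$outcomes$woman_id, base$woman_id), ,
               drop = FALSE]
  rownames(base) <- NULL
  base
}

# Predicted tau-year risks from each woman's baseline mammogram.
baseline_risks <- function(fit, cohort, tau) {
  base <- baseline_profiles(cohort)
  prof <- risk_profile(age = base$age_at_visit,
                       family_history = base$family_history,
                       bbd_category = base$bbd_category,
                       mammo_feature = base$mammo_feature)
  pr <- suppressWarnings(predict_risk(fit, prof, horizons = tau))
  pr$risk[order(pr$profile)]
}

#' Overall calibration at one horizon
#'
#' Expected rate = mean predicted `tau`-year risk from each validation
#' woman's baseline mammogram; observed rate = woman-level KM cumulative
#' incidence at `tau`; ratio and CI per [eo_ratio()].
#'
#' @param cohort validation `screening_cohort`.
#' @param fit a `pc_cox_fit` (from the estimation subcohort).
#' @param tau horizon in years.
#' @param ci CI variant passed to [eo_ratio()].
#' @return a `calibration_result`.
#' @export
overall_calibration <- function(cohort, fit, tau,
                                ci = c("lognormal", "exact")) {
  risks <- baseline_risks(fit, cohort, tau)
  obs <- observed_risk_km(cohort, tau)
  eo_ratio(mean(risks), obs$incidence, obs$O, tau = tau,
           subgroup = "overall", ci = match.arg(ci))
}

#' Calibration within baseline risk-factor subgroups
#'
#' @param cohort validation `screening_cohort`.
#' @param fit a `pc_cox_fit`.
#' @param tau horizon in years (10 by default, the reported balance
#'   between events accrued and follow-up available).
#' @param grouping one of `"age_band"`, `"family_history"`,
#'   `"bbd_category"`, `"mammo_feature"`, evaluated at the baseline
#'   mammogram.
#' @param ci CI variant passed to [eo_ratio()].
#' @return data.frame of `calibration_result` rows, one per level
#'   (levels with no observed events keep an `NA` row).
#' @export
subgroup_calibration <- function(cohort, fit, tau = 10,
                                 grouping = c("age_band",
                                              "family_history",
                                              "bbd_category",
                                              "mammo_feature"),
                                 ci = c("lognormal", "exact")) {
  grouping <- match.arg(grouping)
  ci <- match.arg(ci)
  base <- baseline_profiles(cohort)
  g <- switch(grouping,
              age_band = age_band(base$age_at_visit),
              family_history = factor(
                ifelse(base$family_history == 1, "yes", "no"),
                levels = c("no", "yes")),
              bbd_category = factor(base$bbd_category,
                                    levels = BBD_LEVELS),
              mammo_feature = factor(base$mammo_feature,
                                     levels = FEATURE_LEVELS))
  risks <- baseline_risks(fit, cohort, tau)
  rows <- list()
  for (lv in levels(g)) {
    sel <- !is.na(g) & g == lv
    if (!any(sel)) {
      rows[[lv]] <- eo_ratio(NA_real_, 0, 0, tau = tau, subgroup = lv)
      next
    }
    sub <- screening_cohort(
      cohort$visits[cohort$visits$woman_id %in%
                      cohort$outcomes$woman_id[sel], , drop = FALSE],
      cohort$outcomes[sel, , drop = FALSE])
    obs <- observed_risk_km(sub, tau)
    rows[[lv]] <- eo_ratio(mean(risks[sel]), obs$incidence, obs$O,
                           tau = tau, subgroup = lv, ci = ci)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$grouping <- grouping
  out
}

#' Assemble and write the validation report tables
#'
#' One calibration + discrimination row per horizon, a subgroup
#' calibration block at a chosen horizon, and risk-distribution bins.
#'
#' @param calibration data.frame of per-horizon `calibration_result`
#'   rows.
#' @param discrimination data.frame of per-horizon
#'   `discrimination_result` rows.
#' @param subgroups data.frame from [subgroup_calibration()] (optional).
#' @param bins data.frame of [risk_distribution()] tables with a
#'   `horizon` column (optional).
#' @param dir output directory; when non-`NULL`, writes `table3.csv`,
#'   `table4.csv`, `fig1_bins.csv`.
#' @return list with `table3`, `table4`, `fig1_bins` data.frames.
#' @export
validation_report <- function(calibration, discrimination,
                              subgroups = NULL, bins = NULL,
                              dir = NULL) {
  horizons <- sort(unique(calibration$horizon))
  t3 <- merge(
    calibration[c("horizon", "O", "E", "observed_rate", "eo_ratio",
                  "ci_low", "ci_high")],
    discrimination[c("horizon", "auc", "ci_low", "ci_high", "n_cases",
                     "n_controls")],
    by = "horizon", suffixes = c("_eo", "_auc"), all = TRUE)
  t3 <- t3[order(t3$horizon), , drop = FALSE]
  rownames(t3) <- NULL
  t4 <- if (is.null(subgroups)) t3[0, 0] else subgroups
  fig1 <- if (is.null(bins)) NULL else bins
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(t3, file.path(dir, "table3.csv"), row.names = FALSE)
    utils::write.csv(t4, file.path(dir, "table4.csv"), row.names = FALSE)
    if (!is.null(fig1))
      utils::write.csv(fig1, file.path(dir, "fig1_bins.csv"),
                       row.names = FALSE)
  }
  list(table3 = t3, table4 = t4, fig1_bins = fig1)
}
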