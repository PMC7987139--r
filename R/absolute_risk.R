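# Absolute cumulative risk from a fitted partly conditional model.
#
# A fitted model predicts, for a woman who is cancer-free at a landmark
# with covariate profile Z, the probability of a breast cancer diagnosis
# within the next tau years as
#   risk(tau | Z) = 1 - exp(-Lambda0(tau) * exp(beta'Z)),
# with Lambda0 the Breslow baseline cumulative hazard on the
# residual-time axis. The exponential (rather than product-limit) form
# differs by less than 1e-4 at screening-program event rates.

#' Construct risk profiles
#'
#' @param age age in years at the landmark (a warning is issued outside
#'   the 50-69 screening range).
#' @param family_history 0/1.
#' @param bbd_category,mammo_feature category labels as in
#'   [screening_cohort()].
#' @return data.frame of class `risk_profile`.
#' @export
risk_profile <- function(age, family_history, bbd_category = "none",
                         mammo_feature = "none") {
  df <- data.frame(age = age, family_history = family_history,
                   bbd_category = as.character(bbd_category),
                   mammo_feature = as.character(mammo_feature),
                   stringsAsFactors = FALSE)
  if (any(!(df$bbd_category %in% BBD_LEVELS)) ||
      any(!(df$mammo_feature %in% FEATURE_LEVELS)))
    sr_stop("unknown category in risk profile", "predict", "EENUM")
  if (any(!(df$family_history %in% c(0, 1))))
    sr_stop("family_history must be 0/1", "predict", "EENUM")
  if (any(df$age < 50 | df$age >= 70))
    warning("age outside the supported 50-69 screening range")
  class(df) <- c("risk_profile", "data.frame")
  df
}

#' Predict absolute cumulative breast-cancer risk
#'
#' @param fit a `pc_cox_fit`.
#' @param profile a [risk_profile()] (one or more rows).
#' @param horizons prediction horizons in years, nonnegative; default
#'   the biennial grid 2, 4, ..., 20.
#' @return data.frame with one row per profile x horizon: `profile`
#'   (row index), `horizon`, `risk`, `extrapolated` (`TRUE` when the
#'   horizon exceeds the support of the baseline hazard, in which case
#'   the risk at the last observed step is reported).
#' @examples
#' sim <- simulate_cohort(sim_config(n_women = 2000, seed = 3))
#' fit <- fit_pc_cox(build_stacked(apply_exclusions(sim$cohort)))
#' prof <- risk_profile(age = 57, family_history = 1,
#'                      bbd_category = "proliferative")
#' predict_risk(fit, prof, horizons = c(2, 10))
#' @export
predict_risk <- function(fit, profile, horizons = seq(2, 20, by = 2)) {
  stopifnot(inherits(fit, "pc_cox_fit"))
  if (any(horizons < 0))
    sr_stop("horizons must be >= 0", "predict", "EHORIZON")
  bh <- fit$baseline_cum_hazard
  if (is.null(bh)) sr_stop("fit has no baseline hazard", "predict",
                           "ESPEC")
  sup <- max(bh$time)
  if (any(horizons > sup))
    warning(sprintf(
      "horizon beyond the %.3g-year support of the baseline hazard; reporting the risk at the last observed step",
      sup))
  Lfun <- stats::stepfun(bh$time, c(0, bh$cum_hazard))
  stub <- data.frame(age_at_visit = profile$age,
                     family_history = profile$family_history,
                     bbd_category = profile$bbd_category,
                     mammo_feature = profile$mammo_feature)
  X <- build_design(stub, fit$covariate_spec)
  X <- X[, names(fit$beta), drop = FALSE]
  rel <- exp(drop(X %*% fit$beta))
  out <- expand.grid(profile = seq_len(nrow(profile)),
                     horizon = horizons)
  out$risk <- 1 - exp(-Lfun(out$horizon) * rel[out$profile])
  out$extrapolated <- out$horizon > sup
  out[order(out$profile, out$horizon), , drop = FALSE]
}

#' Bin a population of risk estimates
#'
#' @param risks numeric vector, one predicted risk per woman at a fixed
#'   horizon.
#' @param bin_edges strictly increasing interior cut points on the
#'   probability scale; if `NULL`, defaults by `horizon`: `c(0.015,
#'   0.02)` at 10 years (<1.5%, 1.5-2%, >2%) and `c(0.03, 0.05, 0.07)`
#'   at 20 years; `c(0.003, 0.004)` at 2 years.
#' @param horizon used only to pick default edges.
#' @return data.frame with `bin` label, `lower`, `upper`, `count`,
#'   `proportion` (proportions sum to 1).
#' @export
risk_distribution <- function(risks, bin_edges = NULL, horizon = NULL) {
  if (!length(risks))
    sr_stop("no risks to bin", "report", "EEMPTY")
  if (is.null(bin_edges)) {
    if (is.null(horizon))
      sr_stop("either bin_edges or horizon is required", "report",
              "ESPEC")
    bin_edges <- switch(as.character(horizon),
                        `2` = c(0.003, 0.004),
                        `10` = c(0.015, 0.02),
                        `20` = c(0.03, 0.05, 0.07),
                        sr_stop(paste("no default bin edges at horizon",
                                      horizon), "report", "ESPEC"))
  }
  if (is.unsorted(bin_edges, strictly = TRUE))
    sr_stop("bin_edges must be strictly increasing", "report", "ESPEC")
  edges <- c(0, bin_edges, 1)
  idx <- cut(risks, breaks = edges, include.lowest = TRUE, right = FALSE)
  cnt <- as.vector(table(idx))
  lab <- c(sprintf("<%g%%", 100 * bin_edges[1]),
           if (length(bin_edges) > 1)
             sprintf("%g-%g%%", 100 * utils::head(bin_edges, -1),
                     100 * bin_edges[-1]),
           sprintf(">%g%%", 100 * bin_edges[length(bin_edges)]))
  data.frame(bin = lab,
             lower = utils::head(edges, -1),
             upper = edges[-1],
             count = cnt,
             proportion = cnt / length(risks),
             stringsAsFactors = FALSE)
}
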