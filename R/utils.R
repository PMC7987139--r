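#' @keywords internal
"_PACKAGE"

# Canonical category levels for the three screening risk factors.
BBD_LEVELS <- c("none", "prior_biopsy_unknown", "non_proliferative",
                "proliferative")
FEATURE_LEVELS <- c("none", "mass", "calcifications", "asymmetry",
                    "architectural_distortion", "multiple")
AGE_BAND_BREAKS <- c(50, 55, 60, 65, 70)
AGE_BAND_LABELS <- c("50-54", "55-59", "60-64", "65-69")

# Age (years) subtracted from the continuous age term before fitting.
# Keeps the exponentiated linear predictor well scaled; hazard ratios are
# unaffected and the baseline hazard refers to this age.
AGE_CENTER <- 59.5

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Signal a classed pipeline error
#'
#' Errors raised by the package carry a `stage` and machine-readable
#' `code` so that pipeline callers can abort with context.
#' @noRd
sr_stop <- function(message, stage, code, call = NULL) {
  cond <- structure(
    class = c("screenrisk_error", "error", "condition"),
    list(message = sprintf("[stage=%s code=%s] %s", stage, code, message),
         call = call, stage = stage, code = code)
  )
  stop(cond)
}

#' Evaluate an expression under a local RNG seed
#'
#' Restores the caller's random number generator state afterwards, so
#' seeded package operations do not perturb user simulations.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible sub-seed from a base seed
#'
#' One global seed drives every pipeline stage; each stage uses
#' `base + offset` (kept below 2^31) so stages can be rerun in isolation.
#' @noRd
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1009L * offset) %% 2147483647)
}

age_band <- function(age) {
  cut(age, breaks = AGE_BAND_BREAKS, labels = AGE_BAND_LABELS,
      right = FALSE, include.lowest = TRUE)
}
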