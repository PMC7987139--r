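# Fit artifacts: coefficients, covariances and convergence state go to
# JSON; the baseline cumulative hazard steps go to CSV alongside.

#' Write fit artifacts
#'
#' @param fit a `pc_cox_fit`.
#' @param path path of the JSON artifact; the baseline hazard is written
#'   next to it as `<path minus .json>_basehaz.csv`.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "pc_cox_fit"))
  base_path <- sub("\\.json$", "", path)
  obj <- list(
    beta = as.list(fit$beta),
    robust_cov = fit$robust_cov,
    naive_cov = fit$naive_cov,
    loglik = fit$loglik, loglik_null = fit$loglik_null,
    n_records = fit$n_records, n_clusters = fit$n_clusters,
    n_events = fit$n_events, iterations = fit$iterations,
    score_norm = fit$score_norm,
    covariate_spec = fit$covariate_spec,
    dropped_terms = fit$dropped_terms,
    age_center = fit$age_center, flags = fit$flags)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  utils::write.csv(fit$baseline_cum_hazard,
                   paste0(base_path, "_basehaz.csv"), row.names = FALSE)
  invisible(path)
}

#' Read fit artifacts written by [write_fit()]
#'
#' @param path path of the JSON artifact.
#' @return a `pc_cox_fit`.
#' @export
read_fit <- function(path) {
  if (!file.exists(path))
    sr_stop(paste("fit artifact not found:", path), "load", "ENOENT")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- unlist(obj$beta)
  nm <- names(beta)
  rc <- matrix(unlist(obj$robust_cov), length(beta), byrow = TRUE,
               dimnames = list(nm, nm))
  nc <- matrix(unlist(obj$naive_cov), length(beta), byrow = TRUE,
               dimnames = list(nm, nm))
  bh <- utils::read.csv(paste0(sub("\\.json$", "", path),
                               "_basehaz.csv"))
  structure(list(
    beta = beta, robust_cov = rc, naive_cov = nc,
    baseline_cum_hazard = bh,
    loglik = obj$loglik, loglik_null = obj$loglik_null,
    n_records = obj$n_records, n_clusters = obj$n_clusters,
    n_events = obj$n_events, iterations = obj$iterations,
    score_norm = obj$score_norm,
    covariate_spec = obj$covariate_spec,
    dropped_terms = obj$dropped_terms %||% character(0),
    age_center = obj$age_center, flags = obj$flags %||% character(0)),
    class = "pc_cox_fit")
}
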