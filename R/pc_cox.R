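# Partly conditional Cox model on stacked woman-visit records.
#
# Each stacked record contributes a partial-likelihood term on the
# residual-time axis (time since its landmark), with covariates frozen at
# the landmark. Records are treated as working-independent; all
# within-woman dependence is absorbed by a Huber sandwich variance
# clustered on woman_id. Ties are handled by the Efron approximation.
# The estimating equation is maximized by Newton-Raphson with
# step-halving.

#' Build the model design matrix from stacked records
#'
#' Age enters as a continuous linear term centered at 59.5 years;
#' categorical factors expand to treatment dummies with reference levels
#' "no family history", "no BBD", and "no feature".
#' @noRd
build_design <- function(stacked, covariate_spec) {
  cols <- list()
  for (term in covariate_spec) {
    if (term == "age") {
      cols[["age"]] <- stacked$age_at_visit - AGE_CENTER
    } else if (term == "family_history") {
      cols[["family_history"]] <- as.numeric(stacked$family_history)
    } else if (term == "bbd_category") {
      f <- factor(stacked$bbd_category, levels = BBD_LEVELS)
      for (lv in BBD_LEVELS[-1])
        cols[[paste0("bbd_", lv)]] <- as.numeric(f == lv)
    } else if (term == "mammo_feature") {
      f <- factor(stacked$mammo_feature, levels = FEATURE_LEVELS)
      for (lv in FEATURE_LEVELS[-1])
        cols[[paste0("mammo_", lv)]] <- as.numeric(f == lv)
    } else {
      sr_stop(paste("unknown model term:", term), "fit", "ESPEC")
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

# Risk-set sums and Efron tie structure shared by the likelihood,
# baseline-hazard and residual computations.
#
# Returns, per "slot" (one per event at each unique event time, with the
# Efron fraction f = l/d subtracted from the tied-death sums):
#   S0s (scalar), S1s (p-vector), S2s (packed symmetric p x p)
# Data-dependent structure shared by every evaluation of the partial
# likelihood: descending-time sort, risk-set boundaries at the unique
# event times, and the Efron tie layout. Computed once per fit.
cox_prep <- function(y, d, X, ties = "efron") {
  n <- length(y)
  p <- ncol(X)
  ord <- order(-y)
  ys <- y[ord]
  Xs <- X[ord, , drop = FALSE]
  ev <- which(d == 1)
  ut <- sort(unique(y[ev]))
  K <- length(ut)
  cnt <- n - findInterval(ut, rev(ys), left.open = TRUE)  # |{y >= ut_k}|
  ii <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  # segment layout: rows of the descending sort cut at the (strictly
  # increasing) boundaries rev(cnt); one rowsum pass per evaluation
  # replaces full cumulative sums
  bnd <- rev(cnt)
  m1 <- bnd[K]
  seg <- rep.int(seq_len(K), diff(c(0L, bnd)))
  ke <- match(y[ev], ut)
  dk <- tabulate(ke, nbins = K)
  kk <- rep.int(seq_len(K), dk)
  f <- if (ties == "breslow") rep(0, length(kk))
       else (sequence(dk) - 1) / dk[kk]
  list(n = n, p = p, ord = ord, Xs = Xs, ev = ev, ut = ut, K = K,
       m1 = m1, seg = seg, ke = ke, dk = dk, kk = kk, f = f,
       pairs = ii, Xe = X[ev, , drop = FALSE])
}

# Risk-set sums and Efron tie structure at case weights w = exp(eta).
# Returns, per "slot" (one per event at each unique event time, with the
# Efron fraction f = l/d subtracted from the tied-death sums):
#   S0s (scalar), S1s (p-vector), S2s (packed symmetric p x p)
cox_slots <- function(pp, w) {
  p <- pp$p
  ii <- pp$pairs
  npair <- nrow(ii)
  ws <- w[pp$ord]
  sub <- seq_len(pp$m1)
  M <- matrix(0, pp$m1, 1L + p + npair)
  M[, 1] <- ws[sub]
  for (j in seq_len(p)) M[, 1L + j] <- pp$Xs[sub, j] * M[, 1]
  for (k in seq_len(npair))
    M[, 1L + p + k] <- M[, 1L + ii[k, 1]] * pp$Xs[sub, ii[k, 2]]
  cumG <- apply(rowsum(M, pp$seg), 2, cumsum)
  if (pp$K == 1) cumG <- matrix(cumG, nrow = 1)
  ridx <- pp$K + 1 - seq_len(pp$K)   # event time k sits at boundary K+1-k
  S0 <- cumG[ridx, 1]
  S1 <- cumG[ridx, 1 + seq_len(p), drop = FALSE]
  S2 <- cumG[ridx, -seq_len(1 + p), drop = FALSE]

  we <- w[pp$ev]
  ke <- pp$ke
  s0d <- as.vector(rowsum(we, ke))
  s1d <- rowsum(pp$Xe * we, ke)
  Pd <- pp$Xe[, ii[, 1], drop = FALSE] * pp$Xe[, ii[, 2], drop = FALSE] * we
  s2d <- rowsum(Pd, ke)

  kk <- pp$kk
  f <- pp$f
  S0s <- S0[kk] - f * s0d[kk]
  S1s <- S1[kk, , drop = FALSE] - f * s1d[kk, , drop = FALSE]
  S2s <- S2[kk, , drop = FALSE] - f * s2d[kk, , drop = FALSE]
  list(S0s = S0s, S1s = S1s, S2s = S2s, kk = kk, f = f, ut = pp$ut,
       dk = pp$dk, ke = ke, ev = pp$ev, pairs = ii, p = p)
}

# Log partial likelihood, score and information at beta.
cox_deriv <- function(y, d, X, beta, pp = NULL, ties = "efron") {
  if (is.null(pp)) pp <- cox_prep(y, d, X, ties)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  sl <- cox_slots(pp, w)
  p <- sl$p
  loglik <- sum(eta[d == 1]) - sum(log(sl$S0s))
  M <- sl$S1s / sl$S0s
  score <- colSums(X[d == 1, , drop = FALSE]) - colSums(M)
  packed <- colSums(sl$S2s / sl$S0s)
  info <- matrix(0, p, p)
  info[sl$pairs] <- packed
  info <- info + t(info) - diag(diag(info), p)
  info <- info - crossprod(M)
  list(loglik = loglik, score = score, info = info, slots = sl, w = w)
}

#' Fit a partly conditional Cox model
#'
#' Maximizes the stacked partial likelihood on the residual-time axis
#' (Efron ties, Newton-Raphson with step-halving) and attaches both the
#' naive (inverse-information) covariance and the Huber sandwich
#' covariance clustered on `woman_id`, plus the Breslow baseline
#' cumulative hazard.
#'
#' @param stacked data.frame from [build_stacked()] (columns
#'   `woman_id`, `age_at_visit`, `family_history`, `bbd_category`,
#'   `mammo_feature`, `residual_time`, `event`).
#' @param covariate_spec character vector of model terms; default age
#'   (continuous) plus the three categorical factors.
#' @param tol convergence tolerance on the score (gradient) norm.
#' @param max_iter maximum Newton iterations.
#' @param ties `"efron"` (default; stacked records can tie heavily) or
#'   `"breslow"`.
#' @return An object of class `pc_cox_fit` with elements `beta`,
#'   `robust_cov`, `naive_cov`, `baseline_cum_hazard` (data.frame
#'   `time`/`hazard`/`cum_hazard`), `loglik`, `loglik_null`,
#'   `n_records`, `n_clusters`, `n_events`, `iterations`, `score_norm`,
#'   `flags`.
#' @examples
#' sim <- simulate_cohort(sim_config(n_women = 2000, seed = 3))
#' stacked <- build_stacked(apply_exclusions(sim$cohort))
#' fit <- fit_pc_cox(stacked)
#' fit
#' @export
fit_pc_cox <- function(stacked,
                       covariate_spec = c("age", "family_history",
                                          "bbd_category", "mammo_feature"),
                       tol = 1e-8, max_iter = 50L,
                       ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (sum(stacked$event) < 1)
    sr_stop("no events in stacked records", "fit", "ENOEVENT")
  if (any(stacked$residual_time <= 0))
    sr_stop("residual_time must be > 0", "fit", "EDATA")
  X <- build_design(stacked, covariate_spec)
  keep <- apply(X, 2, function(col) stats::var(col) > 0)
  dropped <- colnames(X)[!keep]
  X <- X[, keep, drop = FALSE]
  if (ncol(X) == 0)
    sr_stop("no estimable model terms", "fit", "ESPEC")
  y <- stacked$residual_time
  d <- stacked$event
  p <- ncol(X)

  beta <- rep(0, p)
  pp <- cox_prep(y, d, X, ties)
  dv <- cox_deriv(y, d, X, beta, pp)
  loglik0 <- dv$loglik
  flags <- character(0)
  iter <- 0L
  repeat {
    gnorm <- sqrt(sum(dv$score^2))
    if (gnorm < tol || iter >= max_iter) break
    iter <- iter + 1L
    step <- tryCatch(solve(dv$info, dv$score), error = function(e) NULL)
    if (is.null(step)) {
      flags <- union(flags, "singular_information")
      step <- dv$score / max(diag(dv$info))
    }
    # step-halving: insist the log partial likelihood does not decrease
    h <- 1
    repeat {
      cand <- beta + h * step
      dvc <- cox_deriv(y, d, X, cand, pp)
      if (is.finite(dvc$loglik) && dvc$loglik >= dv$loglik - 1e-12) break
      h <- h / 2
      if (h < 1e-10) break
    }
    beta <- cand
    dv <- dvc
  }
  if (iter >= max_iter && sqrt(sum(dv$score^2)) >= tol)
    warning("Newton-Raphson did not reach the gradient tolerance in ",
            max_iter, " iterations")
  if (any(abs(beta) > 12)) {
    flags <- union(flags, "possible_separation")
    warning("a coefficient is extreme (|beta| > 12); a level with all ",
            "or no events can make the estimate unbounded")
  }
  names(beta) <- colnames(X)
  naive_cov <- tryCatch(solve(dv$info), error = function(e) {
    flags <<- union(flags, "singular_information")
    matrix(NA_real_, p, p)
  })
  dimnames(naive_cov) <- list(colnames(X), colnames(X))

  fit <- structure(list(
    beta = beta, naive_cov = naive_cov, robust_cov = NULL,
    baseline_cum_hazard = NULL,
    loglik = dv$loglik, loglik_null = loglik0,
    n_records = nrow(X), n_clusters = length(unique(stacked$woman_id)),
    n_events = sum(d), iterations = iter,
    score_norm = sqrt(sum(dv$score^2)),
    covariate_spec = covariate_spec, dropped_terms = dropped,
    age_center = AGE_CENTER, ties = ties, flags = flags),
    class = "pc_cox_fit")

  fit$robust_cov <- robust_sandwich(fit, stacked$woman_id,
                                    stacked = stacked, X = X)
  fit$baseline_cum_hazard <- breslow_baseline(fit, stacked, X = X)
  fit
}

# Efron-weighted score residuals, one row per stacked record.
# r_i = d_i (Z_i - Zbar^E_{k(i)})
#       - w_i (Z_i A(y_i) - B(y_i))
#       + d_i w_i (Z_i a2_{k(i)} - b2_{k(i)})
# where A, B cumulate Sum_l 1/S0_kl and Sum_l Zbar_kl/S0_kl over event
# times <= y_i, and a2/b2 carry the l/d tie weights of the record's own
# event time. Reduces to the standard Cox score residual without ties.
cox_score_residuals <- function(y, d, X, beta, ties = "efron") {
  dv <- cox_deriv(y, d, X, beta, ties = ties)
  sl <- dv$slots
  w <- dv$w
  K <- length(sl$ut)
  p <- sl$p
  inv <- 1 / sl$S0s
  M <- sl$S1s * inv           # Zbar per slot
  a_k <- as.vector(rowsum(inv, sl$kk))
  b_k <- rowsum(sl$S1s * inv^2, sl$kk)
  zebar <- rowsum(M, sl$kk) / sl$dk
  a2_k <- as.vector(rowsum(sl$f * inv, sl$kk))
  b2_k <- rowsum(sl$f * sl$S1s * inv^2, sl$kk)

  cumA <- cumsum(a_k)
  cumB <- apply(b_k, 2, cumsum)
  pos <- findInterval(y, sl$ut)
  A_i <- ifelse(pos > 0, cumA[pmax(pos, 1)], 0)
  B_i <- matrix(0, length(y), p)
  B_i[pos > 0, ] <- cumB[pos[pos > 0], , drop = FALSE]

  r <- -w * (X * A_i - B_i)
  ev <- sl$ev
  r[ev, ] <- r[ev, , drop = FALSE] +
    (X[ev, , drop = FALSE] - zebar[sl$ke, , drop = FALSE]) +
    w[ev] * (X[ev, , drop = FALSE] * a2_k[sl$ke] -
               b2_k[sl$ke, , drop = FALSE])
  colnames(r) <- colnames(X)
  r
}

#' Cluster-robust (Huber sandwich) covariance
#'
#' Computes `A^{-1} B A^{-1}` with `A` the observed information of the
#' stacked partial likelihood and `B` the outer product of per-cluster
#' sums of score residuals, clusters being women.
#'
#' @param fit a `pc_cox_fit`.
#' @param cluster_ids vector of woman identifiers, one per stacked
#'   record, in the order the records were fitted.
#' @param stacked,X internal fast path; when omitted the design is
#'   rebuilt from `stacked`.
#' @return covariance matrix (also stored in the fit by
#'   [fit_pc_cox()]).
#' @export
robust_sandwich <- function(fit, cluster_ids, stacked = NULL, X = NULL) {
  stopifnot(inherits(fit, "pc_cox_fit"))
  if (length(unique(cluster_ids)) < 2)
    sr_stop("need at least 2 clusters for the sandwich", "fit", "ECLUST")
  if (is.null(X)) {
    if (is.null(stacked))
      sr_stop("stacked records required to rebuild the design",
              "fit", "ESPEC")
    X <- build_design(stacked, fit$covariate_spec)
    X <- X[, names(fit$beta), drop = FALSE]
  }
  r <- cox_score_residuals(stacked$residual_time, stacked$event, X,
                           fit$beta, ties = fit$ties %||% "efron")
  G <- rowsum(r, as.character(cluster_ids))
  B <- crossprod(G)
  V <- fit$naive_cov %*% B %*% fit$naive_cov
  dimnames(V) <- dimnames(fit$naive_cov)
  (V + t(V)) / 2
}

#' Breslow baseline cumulative hazard
#'
#' Step-function estimate of the cumulative hazard on the residual-time
#' axis for the reference profile (no risk factors, age 59.5 years),
#' with Efron-consistent increments at tied event times.
#'
#' @param fit a `pc_cox_fit`.
#' @param stacked the stacked records the model was fitted on.
#' @param X internal fast path.
#' @return data.frame with columns `time` (unique event residual-times),
#'   `hazard` (increment) and `cum_hazard`, right-continuous.
#' @export
breslow_baseline <- function(fit, stacked, X = NULL) {
  stopifnot(inherits(fit, "pc_cox_fit"))
  if (is.null(X)) {
    X <- build_design(stacked, fit$covariate_spec)
    X <- X[, names(fit$beta), drop = FALSE]
  }
  y <- stacked$residual_time
  d <- stacked$event
  w <- exp(drop(X %*% fit$beta))
  sl <- cox_slots(cox_prep(y, d, X, fit$ties %||% "efron"), w)
  inc <- as.vector(rowsum(1 / sl$S0s, sl$kk))
  data.frame(time = sl$ut, hazard = inc, cum_hazard = cumsum(inc))
}

#' @export
print.pc_cox_fit <- function(x, ...) {
  cat("Partly conditional Cox fit\n")
  cat(sprintf("  %d records, %d women, %d events; %d iterations, |score|=%.2e\n",
              x$n_records, x$n_clusters, x$n_events, x$iterations,
              x$score_norm))
  se <- sqrt(diag(x$robust_cov))
  tab <- data.frame(coef = x$beta, `exp(coef)` = exp(x$beta),
                    `robust se` = se,
                    z = x$beta / se,
                    p = 2 * stats::pnorm(-abs(x$beta / se)),
                    check.names = FALSE)
  print(tab, digits = 4)
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Hazard-ratio table per covariate level
#'
#' One row per level of each model factor: women-years (sum of stacked
#' residual time observed in that level), stacked event-record count,
#' the adjusted hazard ratio `exp(beta)` and its 95% CI from the robust
#' standard error. Reference levels carry an aHR of 1 by convention.
#'
#' @param fit a `pc_cox_fit`.
#' @param stacked the stacked records the model was fitted on.
#' @return data.frame of class `hr_table`.
#' @export
hazard_ratio_table <- function(fit, stacked) {
  stopifnot(inherits(fit, "pc_cox_fit"))
  se <- sqrt(diag(fit$robust_cov))
  rows <- list()
  add <- function(variable, level, sel, term) {
    wy <- sum(stacked$residual_time[sel])
    ev <- sum(stacked$event[sel])
    if (is.na(term)) {
      ahr <- 1; lo <- NA_real_; hi <- NA_real_
    } else {
      b <- fit$beta[[term]]; s <- se[[term]]
      ahr <- exp(b); lo <- exp(b - 1.96 * s); hi <- exp(b + 1.96 * s)
    }
    rows[[length(rows) + 1]] <<- data.frame(
      variable = variable, level = level, women_years = wy,
      events = ev, aHR = ahr, ci_low = lo, ci_high = hi,
      stringsAsFactors = FALSE)
  }
  if ("family_history" %in% fit$covariate_spec) {
    add("family_history", "no", stacked$family_history == 0, NA)
    add("family_history", "yes", stacked$family_history == 1,
        "family_history")
  }
  if ("bbd_category" %in% fit$covariate_spec) {
    add("bbd_category", "none", stacked$bbd_category == "none", NA)
    for (lv in BBD_LEVELS[-1])
      add("bbd_category", lv, stacked$bbd_category == lv,
          paste0("bbd_", lv))
  }
  if ("mammo_feature" %in% fit$covariate_spec) {
    add("mammo_feature", "none", stacked$mammo_feature == "none", NA)
    for (lv in FEATURE_LEVELS[-1])
      add("mammo_feature", lv, stacked$mammo_feature == lv,
          paste0("mammo_", lv))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("hr_table", "data.frame")
  out
}

#' Wald tests for pairwise interactions
#'
#' For each pair among the base factors (and age), refits the model with
#' product terms and reports the multivariate Wald statistic on the
#' interaction block using the cluster-robust covariance.
#'
#' @param stacked stacked records.
#' @param base_spec base model terms (default the full model).
#' @param pairs optional list of 2-element character vectors; default
#'   all pairs of `base_spec`.
#' @return data.frame with one row per pair: `term_a`, `term_b`, `df`,
#'   `wald`, `p_value`, `note`.
#' @export
test_interactions <- function(stacked,
                              base_spec = c("age", "family_history",
                                            "bbd_category",
                                            "mammo_feature"),
                              pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- utils::combn(base_spec, 2, simplify = FALSE)
  }
  X_base <- build_design(stacked, base_spec)
  X_base <- X_base[, apply(X_base, 2, stats::var) > 0, drop = FALSE]
  y <- stacked$residual_time
  d <- stacked$event
  res <- list()
  for (pr in pairs) {
    Xa <- build_design(stacked, pr[1])
    Xb <- build_design(stacked, pr[2])
    inter <- matrix(NA_real_, nrow(X_base), 0)
    for (i in seq_len(ncol(Xa))) for (j in seq_len(ncol(Xb))) {
      col <- Xa[, i] * Xb[, j]
      cn <- paste0(colnames(Xa)[i], ":", colnames(Xb)[j])
      inter <- cbind(inter, col)
      colnames(inter)[ncol(inter)] <- cn
    }
    # drop inestimable columns: constant, or collinear with the base
    # design (checked via least squares residual variance)
    ok <- logical(ncol(inter))
    for (j in seq_len(ncol(inter))) {
      cj <- inter[, j]
      if (stats::var(cj) <= 0) next
      rsd <- stats::lsfit(cbind(X_base, inter[, which(ok), drop = FALSE]),
                          cj, intercept = TRUE)$residuals
      ok[j] <- mean(rsd^2) > 1e-10 * stats::var(cj)
    }
    note <- ""
    if (!any(ok)) {
      res[[length(res) + 1]] <- data.frame(
        term_a = pr[1], term_b = pr[2], df = 0L, wald = NA_real_,
        p_value = NA_real_,
        note = "interaction collinear with main effects or empty",
        stringsAsFactors = FALSE)
      next
    }
    inter <- inter[, ok, drop = FALSE]
    # events must occur in the interaction cells for estimability
    ev_in <- colSums(inter[d == 1, , drop = FALSE] != 0)
    if (any(ev_in == 0)) {
      inter <- inter[, ev_in > 0, drop = FALSE]
      note <- "cells without events dropped"
      if (ncol(inter) == 0) {
        res[[length(res) + 1]] <- data.frame(
          term_a = pr[1], term_b = pr[2], df = 0L, wald = NA_real_,
          p_value = NA_real_, note = "no events in interaction cells",
          stringsAsFactors = FALSE)
        next
      }
    }
    aug <- cbind(X_base, inter)
    fit <- tryCatch(
      fit_raw_cox(y, d, aug, stacked$woman_id),
      error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(fit$beta))) {
      res[[length(res) + 1]] <- data.frame(
        term_a = pr[1], term_b = pr[2], df = 0L, wald = NA_real_,
        p_value = NA_real_, note = "interaction fit failed",
        stringsAsFactors = FALSE)
      next
    }
    idx <- seq(ncol(X_base) + 1, ncol(aug))
    bI <- fit$beta[idx]
    VI <- fit$robust_cov[idx, idx, drop = FALSE]
    W <- tryCatch(drop(t(bI) %*% solve(VI, bI)), error = function(e) NA)
    df <- length(idx)
    res[[length(res) + 1]] <- data.frame(
      term_a = pr[1], term_b = pr[2], df = df, wald = W,
      p_value = if (is.na(W)) NA_real_ else
        stats::pchisq(W, df, lower.tail = FALSE),
      note = note, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Bare-matrix fit used internally (interaction refits); same engine.
fit_raw_cox <- function(y, d, X, cluster, tol = 1e-8, max_iter = 50L) {
  p <- ncol(X)
  beta <- rep(0, p)
  pp <- cox_prep(y, d, X)
  dv <- cox_deriv(y, d, X, beta, pp)
  iter <- 0L
  repeat {
    if (sqrt(sum(dv$score^2)) < tol || iter >= max_iter) break
    iter <- iter + 1L
    step <- solve(dv$info, dv$score)
    h <- 1
    repeat {
      cand <- beta + h * step
      dvc <- cox_deriv(y, d, X, cand, pp)
      if (is.finite(dvc$loglik) && dvc$loglik >= dv$loglik - 1e-12) break
      h <- h / 2
      if (h < 1e-10) break
    }
    beta <- cand; dv <- dvc
  }
  naive <- solve(dv$info)
  r <- cox_score_residuals(y, d, X, beta)
  G <- rowsum(r, as.character(cluster))
  V <- naive %*% crossprod(G) %*% naive
  list(beta = beta, naive_cov = naive, robust_cov = (V + t(V)) / 2,
       iterations = iter, score_norm = sqrt(sum(dv$score^2)))
}

#' Log-minus-log proportional-hazards diagnostics
#'
#' Kaplan-Meier survivor curves per level of one covariate on the
#' stacked records, transformed to `log(-log S(t))` against `log t`.
#' Under proportional hazards the level curves are parallel (vertical
#' offset equal to the log hazard ratio).
#'
#' @param stacked stacked records.
#' @param covariate one of `"family_history"`, `"bbd_category"`,
#'   `"mammo_feature"`.
#' @param grid_length number of log-time grid points.
#' @return list with `curves` (data.frame `level`, `log_time`,
#'   `loglog_survival`) and `parallelism` (range of the vertical spread
#'   between the outermost curves across the grid; near-constant spread
#'   indicates parallelism). Levels whose survivor never drops below 1
#'   are omitted with a message.
#' @export
ph_diagnostics <- function(stacked, covariate, grid_length = 25L) {
  f <- switch(covariate,
              family_history = factor(ifelse(stacked$family_history == 1,
                                             "yes", "no"),
                                      levels = c("no", "yes")),
              bbd_category = factor(stacked$bbd_category,
                                    levels = BBD_LEVELS),
              mammo_feature = factor(stacked$mammo_feature,
                                     levels = FEATURE_LEVELS),
              sr_stop(paste("unknown covariate:", covariate),
                      "diagnostics", "ESPEC"))
  curves <- list()
  for (lv in levels(f)) {
    sel <- f == lv
    if (!any(sel) || sum(stacked$event[sel]) == 0) {
      if (any(sel)) message("level ", dQuote(lv),
                            " has no events; curve omitted")
      next
    }
    km <- survival::survfit(
      survival::Surv(stacked$residual_time[sel], stacked$event[sel]) ~ 1)
    tt <- km$time[km$n.event > 0]
    ss <- km$surv[km$n.event > 0]
    okk <- ss > 0 & ss < 1
    if (!any(okk)) next
    curves[[lv]] <- data.frame(level = lv, time = tt[okk],
                               surv = ss[okk],
                               stringsAsFactors = FALSE)
  }
  if (!length(curves))
    sr_stop("no level with events", "diagnostics", "ENOEVENT")
  # compare curves on the stable central part of each level's event-time
  # range; the KM tail has few subjects at risk and the transform
  # amplifies its noise
  lo <- max(vapply(curves, function(cc)
    stats::quantile(cc$time, 0.05), 0))
  hi <- min(vapply(curves, function(cc)
    stats::quantile(cc$time, 0.90), 0))
  if (hi <= lo) { lo <- min(vapply(curves, function(cc) min(cc$time), 0))
                  hi <- max(vapply(curves, function(cc) max(cc$time), 0)) }
  grid <- exp(seq(log(lo), log(hi), length.out = grid_length))
  tabs <- lapply(curves, function(cc) {
    sf <- stats::stepfun(cc$time, c(1, cc$surv))
    s <- sf(grid)
    data.frame(level = cc$level[1], log_time = log(grid),
               loglog_survival = log(-log(pmin(s, 1 - 1e-12))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  spread <- NA_real_
  if (length(tabs) > 1) {
    m <- sapply(tabs, function(tb) tb$loglog_survival)
    sp <- apply(m, 1, function(z) diff(range(z[is.finite(z)])))
    sp <- sp[is.finite(sp)]
    if (length(sp)) spread <- diff(range(sp))
  }
  list(curves = out, parallelism = spread)
}
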