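test_that("a label-symmetric dataset gives a zero coefficient", {
  # swapping the two levels maps the dataset onto itself, so the
  # maximizer must be invariant under beta -> -beta
  st <- simple_stacked(time = rep(1:4, each = 2), event = rep(1, 8),
                       z = rep(c(0, 1), 4))
  fit <- fit_pc_cox(st, covariate_spec = "family_history")
  expect_lt(abs(fit$beta[["family_history"]]), 1e-8)
})

test_that("the engine matches a brute-force likelihood scan on a toy", {
  st <- simple_stacked(time = c(1, 2, 3, 4, 5, 6),
                       event = c(1, 0, 1, 1, 0, 1),
                       z = c(1, 1, 0, 1, 0, 0))
  fit <- fit_pc_cox(st, covariate_spec = "family_history")
  scan <- stats::optimize(function(b)
    brute_loglik_1cov(st$residual_time, st$event, st$family_history, b),
    interval = c(-5, 5), maximum = TRUE, tol = 1e-10)
  expect_lt(abs(fit$beta[["family_history"]] - scan$maximum), 1e-6)
  expect_equal(fit$loglik, scan$objective, tolerance = 1e-10)
  # and with tied event times (Efron handling on both sides)
  st2 <- simple_stacked(time = c(1, 1, 2, 2, 3, 4),
                        event = c(1, 1, 1, 0, 1, 1),
                        z = c(1, 0, 1, 1, 0, 0))
  fit2 <- fit_pc_cox(st2, covariate_spec = "family_history")
  scan2 <- stats::optimize(function(b)
    brute_loglik_1cov(st2$residual_time, st2$event, st2$family_history, b),
    interval = c(-5, 5), maximum = TRUE, tol = 1e-10)
  expect_lt(abs(fit2$beta[["family_history"]] - scan2$maximum), 1e-6)
})

test_that("the engine agrees with the reference Cox implementation", {
  set.seed(202)
  for (rep in 1:5) {
    n <- 200
    st <- data.frame(
      woman_id = sprintf("w%03d", 1:n), landmark_time = 0,
      age_at_visit = runif(n, 50, 69),
      family_history = rbinom(n, 1, 0.2),
      bbd_category = sample(c("none", "prior_biopsy_unknown",
                              "non_proliferative", "proliferative"),
                            n, TRUE),
      mammo_feature = sample(c("none", "mass", "calcifications"),
                             n, TRUE),
      residual_time = rexp(n, 0.1), event = rbinom(n, 1, 0.4),
      stringsAsFactors = FALSE)
    fit <- fit_pc_cox(st)
    X <- data.frame(screenrisk:::build_design(st, fit$covariate_spec))
    X$time <- st$residual_time; X$ev <- st$event; X$id <- st$woman_id
    fml <- stats::as.formula(paste(
      "survival::Surv(time, ev) ~",
      paste(names(fit$beta), collapse = "+")))
    ref <- survival::coxph(fml, data = X, ties = "efron",
                           robust = TRUE, cluster = id)
    expect_lt(max(abs(fit$beta - stats::coef(ref))), 1e-6)
    expect_lt(max(abs(sqrt(diag(fit$robust_cov)) -
                        summary(ref)$coefficients[, "robust se"])), 1e-6)
  }
})

test_that("within-cluster record duplication moves naive but not robust SE", {
  # score-doubling algebra: duplicating every record doubles the
  # information and quadruples the clustered outer product, so beta and
  # the sandwich are unchanged while the naive SE shrinks by sqrt(2)
  # (exact under Breslow tie handling, which the duplication induces)
  set.seed(31)
  n <- 150
  st <- simple_stacked(time = rexp(n, 0.2), event = rbinom(n, 1, 0.5),
                       z = rbinom(n, 1, 0.4))
  fit <- fit_pc_cox(st, covariate_spec = "family_history",
                    ties = "breslow")
  dup <- rbind(st, st)   # same woman_id: duplicates live in the cluster
  fit2 <- fit_pc_cox(dup, covariate_spec = "family_history",
                     ties = "breslow")
  expect_lt(abs(fit$beta - fit2$beta), 1e-6)
  expect_lt(abs(sqrt(fit$robust_cov[1, 1]) - sqrt(fit2$robust_cov[1, 1])),
            1e-6)
  expect_equal(sqrt(fit$naive_cov[1, 1]) / sqrt(fit2$naive_cov[1, 1]),
               sqrt(2), tolerance = 1e-6)
})

test_that("sandwich covariance is symmetric positive semidefinite", {
  st <- build_stacked(apply_exclusions(shared_sim()$cohort))
  fit <- fit_pc_cox(st)
  expect_equal(fit$robust_cov, t(fit$robust_cov))
  expect_true(all(eigen(fit$robust_cov, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))
  expect_error(robust_sandwich(fit, rep("w1", fit$n_records)),
               "2 clusters")
})

test_that("convergence diagnostics hold at the optimum", {
  st <- build_stacked(apply_exclusions(shared_sim()$cohort))
  fit <- fit_pc_cox(st)
  expect_lt(fit$score_norm, 1e-8)
  expect_gte(fit$loglik, fit$loglik_null)
  expect_equal(fit$n_records, nrow(st))
  expect_equal(fit$n_clusters, length(unique(st$woman_id)))
})

test_that("hazard-ratio table aggregates women-years and transforms CIs", {
  st <- build_stacked(toy_cohort())
  fit <- fit_pc_cox(st, covariate_spec = c("family_history"))
  tab <- hazard_ratio_table(fit, st)
  fh <- tab[tab$variable == "family_history", ]
  expect_equal(fh$women_years[fh$level == "no"],
               sum(st$residual_time[st$family_history == 0]))
  expect_equal(fh$women_years[fh$level == "yes"],
               sum(st$residual_time[st$family_history == 1]))
  expect_equal(fh$aHR[fh$level == "no"], 1)
  b <- fit$beta[["family_history"]]
  s <- sqrt(fit$robust_cov["family_history", "family_history"])
  expect_equal(fh$aHR[fh$level == "yes"], exp(b))
  expect_equal(fh$ci_low[fh$level == "yes"], exp(b - 1.96 * s))
  expect_equal(fh$ci_high[fh$level == "yes"], exp(b + 1.96 * s))
  # closed-form worked example: beta = ln 2, robust se = 0.1
  expect_equal(round(exp(log(2) - 1.96 * 0.1), 2), 1.64)
  expect_equal(round(exp(log(2) + 1.96 * 0.1), 2), 2.43)
})

test_that("Breslow baseline reduces to Nelson-Aalen at beta = 0", {
  st <- simple_stacked(time = c(1, 2, 2.5, 3, 5, 7),
                       event = c(1, 1, 0, 1, 0, 1),
                       z = c(0, 1, 1, 0, 1, 0))
  fit0 <- null_fit("family_history")
  bh <- breslow_baseline(fit0, st)
  # Nelson-Aalen by hand: d/n at each event time
  at_risk <- sapply(bh$time, function(t) sum(st$residual_time >= t))
  d_k <- sapply(bh$time, function(t)
    sum(st$event == 1 & st$residual_time == t))
  expect_equal(bh$cum_hazard, cumsum(d_k / at_risk))
  expect_true(all(diff(bh$cum_hazard) > 0))
})

test_that("a single event among n records increments the hazard by 1/n", {
  st <- simple_stacked(time = c(4, 5, 6, 7), event = c(1, 0, 0, 0),
                       z = c(0, 1, 0, 1))
  bh <- breslow_baseline(null_fit("family_history"), st)
  expect_equal(bh$cum_hazard, 1 / 4)
  expect_equal(bh$time, 4)
})

test_that("risk predictions are invariant to covariate centering", {
  sim <- shared_sim()
  st <- build_stacked(apply_exclusions(sim$cohort))
  fit <- fit_pc_cox(st)
  shifted <- st
  shifted$age_at_visit <- shifted$age_at_visit + 5
  fit2 <- fit_pc_cox(shifted)
  prof <- risk_profile(age = 62, family_history = 1,
                       bbd_category = "proliferative",
                       mammo_feature = "calcifications")
  prof2 <- prof; prof2$age <- prof2$age + 5
  r1 <- predict_risk(fit, prof, horizons = c(2, 6, 10))
  r2 <- suppressWarnings(predict_risk(fit2, prof2,
                                      horizons = c(2, 6, 10)))
  expect_equal(r1$risk, r2$risk, tolerance = 1e-8)
})

test_that("interaction Wald tests detect product effects and flag collinearity", {
  set.seed(404)
  n <- 1500
  z1 <- rbinom(n, 1, 0.5)
  bbd <- ifelse(rbinom(n, 1, 0.4) == 1, "prior_biopsy_unknown", "none")
  z2 <- as.numeric(bbd != "none")
  lam <- 0.05 * exp(0.3 * z1 + 0.2 * z2 + 1.3 * z1 * z2)
  time <- rexp(n, lam)
  cens <- runif(n, 2, 25)
  st <- simple_stacked(pmin(time, cens), as.numeric(time <= cens), z1)
  st$bbd_category <- bbd
  res <- test_interactions(st, base_spec = c("family_history",
                                             "bbd_category"))
  expect_equal(nrow(res), 1)
  expect_lt(res$p_value, 0.05)

  # a candidate identical to a main effect is collinear
  st$mammo_feature <- ifelse(st$family_history == 1, "mass", "none")
  res2 <- test_interactions(st, base_spec = c("family_history",
                                              "mammo_feature"))
  expect_true(is.na(res2$wald) || res2$df < 5)

  # no generating interaction: the test does not reject wildly
  set.seed(405)
  rej <- 0
  for (r in 1:20) {
    z1 <- rbinom(400, 1, 0.5)
    bbd <- ifelse(rbinom(400, 1, 0.4) == 1, "prior_biopsy_unknown",
                  "none")
    lam <- 0.08 * exp(0.4 * z1 + 0.3 * (bbd != "none"))
    time <- rexp(400, lam)
    cens <- runif(400, 2, 25)
    stn <- simple_stacked(pmin(time, cens), as.numeric(time <= cens), z1)
    stn$bbd_category <- bbd
    p <- test_interactions(stn, base_spec = c("family_history",
                                              "bbd_category"))$p_value
    rej <- rej + (!is.na(p) && p < 0.05)
  }
  expect_lte(rej, 4)   # 20 null replicates at the 5% level
})

test_that("log-minus-log curves are parallel under proportional hazards", {
  set.seed(88)
  n <- 8000
  z <- rep(c(0, 1), each = n / 2)
  time <- rexp(n, 0.1 * 2^z)
  st <- simple_stacked(pmin(time, 15), as.numeric(time <= 15), z)
  diag2 <- ph_diagnostics(st, "family_history")
  cv <- diag2$curves
  a <- cv$loglog_survival[cv$level == "no"]
  b <- cv$loglog_survival[cv$level == "yes"]
  offs <- b - a
  # the KM paths are correlated across the grid, so the mean offset
  # carries a Monte-Carlo error of a few hundredths
  expect_equal(mean(offs), log(2), tolerance = 0.15)
  expect_lt(diag2$parallelism, 0.35)

  # identical groups: offset near zero
  st0 <- simple_stacked(pmin(time, 15), as.numeric(time <= 15),
                        rep(c(0, 1), n / 2))
  d0 <- ph_diagnostics(st0, "family_history")
  c0 <- d0$curves
  expect_lt(abs(mean(c0$loglog_survival[c0$level == "yes"] -
                       c0$loglog_survival[c0$level == "no"])), 0.1)

  # crossing hazards: Weibull shape 3 against exponential
  tw <- rweibull(n / 2, shape = 3, scale = 10)
  tc <- rexp(n / 2, 0.1)
  stx <- simple_stacked(pmin(c(tc, tw), 15),
                        as.numeric(c(tc, tw) <= 15), z)
  dx <- ph_diagnostics(stx, "family_history")
  expect_gt(dx$parallelism, diag2$parallelism)
})
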