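test_that("the split is a reproducible woman-level partition", {
  coh <- shared_sim()$cohort
  small <- screening_cohort(
    coh$visits[coh$visits$woman_id %in% coh$outcomes$woman_id[1:10], ],
    coh$outcomes[1:10, ])
  parts <- split_cohort(small, fraction = 0.6, seed = 4)
  expect_equal(nrow(parts$estimation$outcomes), 6)
  expect_equal(nrow(parts$validation$outcomes), 4)
  expect_length(intersect(parts$estimation$outcomes$woman_id,
                          parts$validation$outcomes$woman_id), 0)
  # visits follow their woman
  expect_true(all(parts$estimation$visits$woman_id %in%
                    parts$estimation$outcomes$woman_id))
  again <- split_cohort(small, fraction = 0.6, seed = 4)
  expect_identical(parts$estimation$outcomes$woman_id,
                   again$estimation$outcomes$woman_id)
  expect_error(split_cohort(small, fraction = 0.001), "empty")
})

test_that("Kaplan-Meier observed incidence matches the hand product", {
  # times {1+, 2, 3+, 4}: S(4) = (1 - 1/3)(1 - 1/1) = 0
  coh <- screening_cohort(
    data.frame(woman_id = c("a", "b", "c", "d"), visit_time = 0,
               age_at_visit = 51:54, family_history = 0,
               bbd_category = "none", mammo_feature = "none"),
    data.frame(woman_id = c("a", "b", "c", "d"), event = c(0, 1, 0, 1),
               end_time = c(1, 2, 3, 4)))
  obs <- observed_risk_km(coh, 4)
  expect_equal(obs$incidence, 1)
  expect_equal(obs$O, 2)
  # without censoring before tau, KM reduces to the empirical fraction
  coh2 <- screening_cohort(
    data.frame(woman_id = letters[1:5], visit_time = 0,
               age_at_visit = 51:55, family_history = 0,
               bbd_category = "none", mammo_feature = "none"),
    data.frame(woman_id = letters[1:5], event = c(1, 1, 0, 0, 0),
               end_time = c(1, 3, 6, 7, 8)))
  expect_equal(observed_risk_km(coh2, 5)$incidence, 2 / 5)
  # zero events
  coh3 <- screening_cohort(
    coh2$visits, transform(coh2$outcomes, event = 0))
  expect_equal(observed_risk_km(coh3, 5)$incidence, 0)
  expect_equal(observed_risk_km(coh3, 5)$O, 0)
  expect_true(observed_risk_km(coh3, 99)$truncated)
})

test_that("E/O ratio reproduces the standardized-ratio closed form", {
  r <- eo_ratio(E = 0.05, observed_rate = 0.05, O = 40)
  expect_equal(r$eo_ratio, 1)
  expect_equal(r$ci_low, exp(-1.96 / sqrt(40)))

  # published worked example: ratio 0.99 with 188 observed events
  ex <- eo_ratio(E = 0.99, observed_rate = 1, O = 188)
  expect_equal(round(ex$eo_ratio, 2), 0.99)
  expect_equal(round(ex$ci_low, 2), 0.86)
  expect_equal(round(ex$ci_high, 2), 1.14)

  # CI width shrinks as O grows
  w <- sapply(c(10, 100, 1000), function(O)
    with(eo_ratio(0.02, 0.02, O), ci_high - ci_low))
  expect_true(all(diff(w) < 0))
  expect_true(with(eo_ratio(0.03, 0.02, 25),
                   ci_low <= eo_ratio && eo_ratio <= ci_high))

  z <- eo_ratio(E = 0.02, observed_rate = 0, O = 0)
  expect_true(is.na(z$eo_ratio))

  ex2 <- eo_ratio(0.02, 0.02, 25, ci = "exact")
  expect_true(ex2$ci_low < 1 && 1 < ex2$ci_high)
})

test_that("AUC agrees with explicit pair enumeration", {
  outcomes <- data.frame(event = c(1, 1, 0, 0, 0),
                         end_time = c(1, 2, 9, 9, 9))
  scores <- c(0.9, 0.7, 0.8, 0.1, 0.2)
  a <- auc_at_horizon(scores, outcomes, tau = 5)
  expect_equal(a$auc, brute_auc(c(0.9, 0.7), c(0.8, 0.1, 0.2)))
  expect_equal(a$auc, 5 / 6)
  expect_equal(a$n_cases, 2)
  expect_equal(a$n_controls, 3)
  # Hanley-McNeil interval from its closed form
  A <- 5 / 6; Q1 <- A / (2 - A); Q2 <- 2 * A^2 / (1 + A)
  se <- sqrt((A * (1 - A) + (2 - 1) * (Q1 - A^2) +
                (3 - 1) * (Q2 - A^2)) / (2 * 3))
  expect_equal(a$ci_high, min(1, A + 1.96 * se))

  # perfect separation and pure ties
  perf <- auc_at_horizon(c(1, 1, 0, 0), data.frame(
    event = c(1, 1, 0, 0), end_time = c(1, 1, 9, 9)), tau = 5)
  expect_equal(perf$auc, 1)
  ties <- auc_at_horizon(rep(0.3, 4), data.frame(
    event = c(1, 1, 0, 0), end_time = c(1, 1, 9, 9)), tau = 5)
  expect_equal(ties$auc, 0.5)
})

test_that("AUC eligibility follows the horizon rule", {
  outcomes <- data.frame(event = c(1, 0, 0, 1),
                         end_time = c(3, 4, 10, 8))
  # tau = 5: woman 1 case; woman 2 censored event-free before 5 ->
  # excluded; woman 3 control; woman 4 event after 5 -> control
  a <- auc_at_horizon(c(4, 3, 2, 1), outcomes, tau = 5)
  expect_equal(a$n_cases, 1)
  expect_equal(a$n_controls, 2)
  none <- auc_at_horizon(c(1, 2), data.frame(event = c(0, 0),
                                             end_time = c(9, 9)), tau = 5)
  expect_true(is.na(none$auc))
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(12)
  outcomes <- data.frame(event = rbinom(300, 1, 0.3),
                         end_time = runif(300, 6, 20))
  scores <- runif(300)
  a1 <- auc_at_horizon(scores, outcomes, tau = 5)
  a2 <- auc_at_horizon(stats::qlogis(scores), outcomes, tau = 5)
  a3 <- auc_at_horizon(100 * scores + 7, outcomes, tau = 5)
  expect_identical(a1$auc, a2$auc)
  expect_identical(a1$auc, a3$auc)
})

test_that("subgroup calibration with one populated level matches overall", {
  sim <- shared_sim()
  coh <- apply_exclusions(sim$cohort)
  parts <- split_cohort(coh, 0.6, seed = 77)
  fit <- fit_pc_cox(build_stacked(parts$estimation))
  val <- parts$validation
  # force a single family-history level in the validation subcohort
  val$visits$family_history <- 0
  val <- screening_cohort(val$visits, val$outcomes)
  sub <- subgroup_calibration(val, fit, tau = 6,
                              grouping = "family_history")
  overall <- overall_calibration(val, fit, tau = 6)
  no <- sub[sub$subgroup == "no", ]
  expect_equal(no$eo_ratio, overall$eo_ratio)
  expect_equal(no$O, overall$O)
  yes <- sub[sub$subgroup == "yes", ]
  expect_true(is.na(yes$eo_ratio))
})

test_that("the report table collects one row per horizon and round-trips", {
  sim <- shared_sim()
  coh <- apply_exclusions(sim$cohort)
  parts <- split_cohort(coh, 0.6, seed = 19)
  fit <- fit_pc_cox(build_stacked(parts$estimation))
  horizons <- seq(2, 20, by = 2)
  calib <- do.call(rbind, lapply(horizons, function(tau)
    overall_calibration(parts$validation, fit, tau)))
  disc <- do.call(rbind, lapply(horizons, function(tau)
    auc_at_horizon(screenrisk:::baseline_risks(fit, parts$validation,
                                               tau),
                   parts$validation$outcomes, tau)))
  dir <- tempfile("report_")
  rep <- validation_report(calib, disc, dir = dir)
  expect_equal(nrow(rep$table3), 10)
  expect_equal(rep$table3$horizon, horizons)
  back <- utils::read.csv(file.path(dir, "table3.csv"))
  expect_equal(back$eo_ratio, rep$table3$eo_ratio, tolerance = 1e-12)
  expect_equal(back$auc, rep$table3$auc, tolerance = 1e-12)

  empty <- validation_report(calib[0, ], disc[0, ], dir = dir)
  expect_equal(nrow(empty$table3), 0)
  expect_equal(nrow(utils::read.csv(file.path(dir, "table3.csv"))), 0)
})
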