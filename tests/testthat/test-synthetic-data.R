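test_that("markov cohorts are deterministic given the scenario and respect record invariants", {
  sc <- markov_scenario(0.03, 0.015, 0.06, n_patients = 300, seed = 11)
  a <- simulate_markov_cohort(sc)
  b <- simulate_markov_cohort(sc)
  expect_identical(a, b)
  expect_silent(validate_patients(a))
  has <- !is.na(a$t_intervention)
  expect_true(all(a$t_end > 0))
  expect_true(all(a$t_intervention[has] <= a$t_end[has]))

  censored <- simulate_markov_cohort(
    markov_scenario(0.03, 0.015, 0.06, n_patients = 300, censor_time = 30, seed = 11))
  expect_true(all(censored$t_end <= 30))
  expect_true(any(!censored$discharged))
  expect_silent(validate_patients(censored))
})

test_that("an impossible intermediate event never appears in the simulation", {
  sc <- markov_scenario(0, 0.02, 0.05, n_patients = 500, seed = 2)
  rec <- simulate_markov_cohort(sc)
  expect_true(all(is.na(rec$t_intervention)))
})

test_that("state-0 sojourns match the exponential mean at large n", {
  sc <- markov_scenario(0.02, 0.01, 0.05, n_patients = 1e5, seed = 4)
  rec <- simulate_markov_cohort(sc)
  sojourn0 <- ifelse(is.na(rec$t_intervention), rec$t_end, rec$t_intervention)
  mu <- 1 / 0.03
  expect_lt(abs(mean(sojourn0) - mu), 3 * mu / sqrt(1e5))
})

test_that("empirical state occupation converges to the Markov occupation probabilities", {
  a01 <- 0.02; a02 <- 0.01; a12 <- 0.05
  rec <- simulate_markov_cohort(markov_scenario(a01, a02, a12, n_patients = 1e5, seed = 8))
  n <- nrow(rec)
  has <- !is.na(rec$t_intervention)
  exit0 <- ifelse(has, rec$t_intervention, rec$t_end)
  r0 <- a01 + a02
  for (t in c(10, 30, 60, 120)) {
    p0 <- exp(-r0 * t)
    p1 <- a01 / (r0 - a12) * (exp(-a12 * t) - exp(-r0 * t))
    f0 <- mean(exit0 > t)
    f1 <- mean(has & rec$t_intervention <= t & rec$t_end > t)
    expect_lt(abs(f0 - p0), 3 * sqrt(p0 * (1 - p0) / n) + 1e-12)
    expect_lt(abs(f1 - p1), 3 * sqrt(p1 * (1 - p1) / n) + 1e-12)
  }
})

test_that("the closed-form change in LOS matches its defining quantities", {
  # hand-frozen value: 1/0.05 - (1/0.03 + 0.02/(0.03*0.05)) = -26.666...
  expect_equal(closed_form_clos(0.02, 0.01, 0.05), -80 / 3, tolerance = 1e-12)

  # no change in discharge hazard => no change in LOS, for any entry hazard
  for (seed in 1:20) {
    set.seed(seed)
    a01 <- runif(1, 0.001, 0.2)
    a <- runif(1, 0.001, 0.2)
    expect_equal(closed_form_clos(a01, a, a), 0, tolerance = 1e-12)
  }

  # strictly decreasing in the post-event discharge hazard
  vals <- vapply(c(0.02, 0.05, 0.1, 0.5), function(a12)
    closed_form_clos(0.02, 0.01, a12), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("the closed form agrees with direct simulation of the two counterfactual cohorts", {
  # cohort forced into the post-event state at time 0 vs the usual dynamics
  set.seed(91)
  n <- 1e5
  forced <- stats::rexp(n, 0.05)
  usual <- simulate_markov_cohort(markov_scenario(0.02, 0.01, 0.05, n_patients = n, seed = 92))
  est <- mean(forced) - mean(usual$t_end)
  se <- sqrt(var(forced) / n + var(usual$t_end) / n)
  expect_lt(abs(est - closed_form_clos(0.02, 0.01, 0.05)), 3 * se)
})

test_that("study-like cohorts reproduce the target sample structure", {
  rec <- simulate_study_cohort(study_scenario())
  expect_identical(nrow(rec), 112L)
  expect_identical(sum(rec$cohort == "intervention_era"), 52L)
  expect_identical(sum(rec$cohort == "control"), 60L)
  expect_true(all(is.na(rec$t_intervention[rec$cohort == "control"])))
  expect_lt(abs(mean(rec$t_end) - 70), 10)
  tint <- rec$t_intervention[!is.na(rec$t_intervention)]
  expect_lt(abs(median(tint) - 25), 10)
  # stays span short to very long, as in the emulated sample (3 to 422 days)
  expect_lt(min(rec$t_end), 21)
  expect_gt(max(rec$t_end), 150)
  # Table-1-style demographics
  expect_identical(sum(rec$sex == "female" & rec$cohort == "control"), 23L)
  expect_identical(sum(rec$sex == "female" & rec$cohort == "intervention_era"), 23L)
  expect_identical(simulate_study_cohort(study_scenario()), rec)
})

test_that("degenerate single-cohort scenarios simulate without error", {
  rec <- simulate_study_cohort(study_scenario(n_control = 0))
  expect_identical(nrow(rec), 52L)
  expect_true(all(rec$cohort == "intervention_era"))
})

test_that("infeasible calibration tolerances fail naming the violated summary", {
  sc <- study_scenario(tolerances = list(mean_los = 0.001, median_t_intervention = 10))
  expect_error(simulate_study_cohort(sc), "mean LOS",
               class = "bedrelease_error_calibration")
})

test_that("integer-rounding mode produces tied whole-day times that still validate", {
  rec <- simulate_markov_cohort(
    markov_scenario(0.05, 0.02, 0.08, n_patients = 400, seed = 5), round_days = TRUE)
  expect_true(all(rec$t_end == round(rec$t_end)))
  expect_true(any(duplicated(rec$t_end)))
  expect_silent(validate_patients(rec))
  has <- !is.na(rec$t_intervention)
  expect_true(all(rec$t_intervention[has] <= rec$t_end[has]))
  expect_true(all(rec$t_intervention[has] >= 1))
})

test_that("invalid scenario parameters are rejected", {
  expect_error(markov_scenario(-0.01, 0.02, 0.05), class = "bedrelease_error_parameter")
  expect_error(markov_scenario(0.01, 0, 0.05), class = "bedrelease_error_parameter")
  expect_error(markov_scenario(0.01, 0.02, 0.05, n_patients = 0),
               class = "bedrelease_error_parameter")
  expect_error(markov_scenario(0.01, 0.02, 0.05, censor_time = -1),
               class = "bedrelease_error_parameter")
  expect_error(closed_form_clos(0, 0.02, 0.05), class = "bedrelease_error_parameter")
  expect_error(study_scenario(age_control = c(69, 0)), class = "bedrelease_error_parameter")
})
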