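test_that("fixed inputs give the deterministic product and the published arithmetic", {
  cfg <- econ_config(patients_per_month_low = 25, patients_per_month_high = 25,
                     n_sims = 100, seed = 1)
  res <- run_monte_carlo(rep(33, 5), cfg)
  expect_true(all(res$sims$annual_bed_days == 33 * 25 * 12))
  expect_equal(unique(res$sims$annual_bed_days), 9900)

  # 228876 / 9999 = 22.89, the headline cost per bed day of about $23
  res2 <- run_monte_carlo(rep(9999 / 300, 5), cfg)
  expect_equal(unique(res2$sims$cost_per_bed_day), 228876 / 9999, tolerance = 1e-12)
  expect_equal(round(unique(res2$sims$cost_per_bed_day)), 23)
})

test_that("draws supported on [5, 70] always meet the $216 willingness to pay", {
  set.seed(2)
  draws <- runif(500, 5, 70)
  res <- run_monte_carlo(draws, econ_config(n_sims = 1000, seed = 3))
  # worst case: 228876 / (5 * 20 * 12) = 190.7 < 216
  expect_true(all(res$sims$cost_per_bed_day < 216))
  expect_equal(res$p_meets_wtp, 1)
})

test_that("the simulation is deterministic given the config seed", {
  draws <- c(10, 20, 33, 50)
  a <- run_monte_carlo(draws, econ_config(n_sims = 200, seed = 5))
  b <- run_monte_carlo(draws, econ_config(n_sims = 200, seed = 5))
  expect_identical(a$sims, b$sims)
})

test_that("summary rows behave like Monte Carlo moments", {
  res <- run_monte_carlo(rep(33, 3),
                         econ_config(patients_per_month_low = 25,
                                     patients_per_month_high = 25, n_sims = 50, seed = 7))
  td <- tidy(res)
  const <- td[td$quantity == "annual_bed_days", ]
  expect_equal(const$sd, 0)
  expect_equal(const$min, const$mean)
  expect_equal(const$max, const$mean)

  # patients per month ~ U(20,30): mean near 25, SD near 10/sqrt(12) ~ 2.9
  res2 <- run_monte_carlo(rep(33, 3), econ_config(n_sims = 1000, seed = 8))
  td2 <- tidy(res2, rounded = TRUE)
  m <- td2[td2$quantity == "patients_per_month", ]
  expect_equal(m$mean, 25)
  expect_equal(m$sd, 3)
  expect_equal(glance(res2)$component_cost, 229000)
  expect_equal(glance(res2)$total_cost, 228876)
})

test_that("simulations releasing no bed days are excluded from costs but conserved", {
  draws <- c(-5, 0, 10, 33)
  res <- run_monte_carlo(draws, econ_config(n_sims = 500, seed = 9))
  expect_gt(res$n_nonpositive, 0)
  usable <- sum(res$sims$bed_days_per_patient > 0)
  expect_identical(usable + res$n_nonpositive, 500L)
  expect_true(all(is.na(res$sims$cost_per_bed_day[res$sims$bed_days_per_patient <= 0])))
  # non-positive draws never meet the criterion
  cc <- ceac(res, wtp_grid = c(1e6))
  expect_equal(cc$probability, usable / 500)
  expect_error(run_monte_carlo(c(-1, 0), econ_config()),
               class = "bedrelease_error_econ_undefined")
})

test_that("the CEAC is monotone, anchored at zero, and consistent with p_meets_wtp", {
  set.seed(10)
  res <- run_monte_carlo(rnorm(300, 33, 12), econ_config(n_sims = 400, seed = 11))
  cc <- ceac(res, wtp_grid = seq(0, 400, by = 10))
  expect_true(all(diff(cc$probability) >= 0))
  expect_equal(cc$probability[cc$wtp == 0], 0)
  expect_equal(cc$probability[cc$wtp == 400],
               sum(res$sims$bed_days_per_patient > 0 &
                     res$sims$cost_per_bed_day < 400) / 400)
  at216 <- ceac(res, wtp_grid = 216)
  expect_equal(at216$probability, res$p_meets_wtp)
  huge <- ceac(res, wtp_grid = 1e9)
  expect_equal(huge$probability, 1 - res$n_nonpositive / 400)
})

test_that("doubling the total cost exactly doubles every cost per bed day", {
  draws <- c(10, 20, 33, 50)
  res1 <- run_monte_carlo(draws, econ_config(total_cost_override = 228876,
                                             n_sims = 300, seed = 12))
  res2 <- run_monte_carlo(draws, econ_config(total_cost_override = 2 * 228876,
                                             n_sims = 300, seed = 12))
  expect_equal(res2$sims$cost_per_bed_day, 2 * res1$sims$cost_per_bed_day)
  # the CEAC shifts accordingly: P2(2w) = P1(w)
  w <- seq(10, 500, by = 10)
  expect_equal(ceac(res2, 2 * w)$probability, ceac(res1, w)$probability)
})

test_that("pairing and discretisation options change the sampling scheme only", {
  draws <- seq(5, 70, length.out = 100)
  one <- run_monte_carlo(draws, econ_config(n_sims = 100, pairing = "one_to_one", seed = 13))
  expect_equal(one$sims$bed_days_per_patient, draws)
  expect_error(run_monte_carlo(draws[1:50],
                               econ_config(n_sims = 100, pairing = "one_to_one")),
               class = "bedrelease_error_parameter")
  disc <- run_monte_carlo(draws, econ_config(n_sims = 200, discrete_patients = TRUE, seed = 14))
  expect_true(all(disc$sims$patients_per_month %in% 20:30))
})

test_that("config invariants are enforced", {
  expect_error(econ_config(patients_per_month_low = 31), class = "bedrelease_error_parameter")
  expect_error(econ_config(cost_components = numeric(0)), class = "bedrelease_error_parameter")
  expect_error(econ_config(n_sims = 0), class = "bedrelease_error_parameter")
  expect_equal(total_cost(econ_config(total_cost_override = NULL)), 229000)
})
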