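test_that("an origin at or beyond the last event time returns an identity grid", {
  tab <- build_transition_table(make_records(t_int = 10, t_end = 40))
  expect_message(P <- aalen_johansen(tab, s = 50), "identity")
  expect_identical(nrow(P), 1L)
  expect_equal(P$p00, 1)
  expect_equal(P$p11, 1)
})

test_that("a single fully observed trajectory is certainly discharged by its end", {
  tab <- build_transition_table(make_records(t_int = 10, t_end = 40))
  P <- aalen_johansen(tab, s = 0)
  expect_equal(P$p02[P$time == 40], 1)
  expect_equal(P$p12[P$time == 40], 1)
})

test_that("with no intermediate events P00(0,.) equals the Kaplan-Meier estimator exactly", {
  skip_if_not_installed("survival")
  set.seed(33)
  n <- 200
  t_end <- round(rexp(n, 0.05), 1) + 0.1
  disc <- runif(n) > 0.25
  rec <- make_records(t_int = rep(NA_real_, n), t_end = t_end, discharged = disc)
  P <- aalen_johansen(build_transition_table(rec), s = 0)
  km <- survival::survfit(survival::Surv(t_end, disc) ~ 1)
  km_at <- summary(km, times = P$time[-1], extend = TRUE)$surv
  expect_equal(P$p00[-1], km_at, tolerance = 1e-14)
})

test_that("transition probabilities are row-stochastic with monotone absorption", {
  for (seed in 1:20) {
    rec <- random_cohort(n = sample(3:25, 1), seed = 100 + seed)
    tab <- build_transition_table(rec)
    for (s in c(0, tab$time[1], stats::median(tab$time))) {
      P <- suppressMessages(aalen_johansen(tab, s = s))
      expect_true(all(P$p00 + P$p01 + P$p02 - 1 < 1e-9 &
                        P$p00 + P$p01 + P$p02 - 1 > -1e-9))
      expect_true(all(abs(P$p11 + P$p12 - 1) < 1e-9))
      probs <- unlist(P[c("p00", "p01", "p02", "p11", "p12")])
      expect_true(all(probs >= -1e-12 & probs <= 1 + 1e-12))
      expect_true(all(diff(P$p02) >= -1e-12)) # state 2 absorbing from state 0
      expect_true(all(diff(P$p12) >= -1e-12))
    }
  }
})

test_that("tiny cohorts match hand-computed product-integral matrices exactly", {
  for (seed in 1:30) {
    rec <- random_cohort(n = sample(1:4, 1), seed = 200 + seed)
    tab <- build_transition_table(rec)
    s_grid <- c(0, tab$time)
    for (s in s_grid) {
      P <- suppressMessages(aalen_johansen(tab, s = s))
      for (i in seq_len(nrow(P))) {
        M <- oracle_P(rec, s, P$time[i])
        expect_equal(unlist(P[i, c("p00", "p01", "p02")]), M[1, 1:3],
                     tolerance = 1e-12, ignore_attr = TRUE)
        expect_equal(unlist(P[i, c("p11", "p12")]), M[2, 2:3],
                     tolerance = 1e-12, ignore_attr = TRUE)
      }
    }
  }
})

test_that("expected LOS handles the trivial grids from the definition", {
  tab <- build_transition_table(make_records(t_int = 10, t_end = 40))
  # no events after s: occupancy stays 1 up to the horizon
  P50 <- suppressMessages(aalen_johansen(tab, s = 50))
  expect_equal(expected_los_given_state(P50, s = 50, j = 0, tau = 80), 80)
  # the single patient is in state 1 at s = 10 and discharged exactly at 40
  P10 <- aalen_johansen(tab, s = 10)
  expect_equal(expected_los_given_state(P10, j = 1, tau = 40), 40)
  expect_equal(expected_los_given_state(P10, j = 1, tau = 10), 10)
})

test_that("expected LOS conditional on the discharged state is rejected", {
  tab <- build_transition_table(make_records(t_int = 10, t_end = 40))
  P <- aalen_johansen(tab, s = 0)
  expect_error(expected_los_given_state(P, j = 2, tau = 40),
               class = "bedrelease_error_state")
})

test_that("expected LOS matches the brute-force step integral on random cohorts", {
  for (seed in 1:10) {
    rec <- random_cohort(n = sample(2:10, 1), seed = 300 + seed)
    tab <- build_transition_table(rec)
    tau <- max(tab$time)
    s <- tab$time[1]
    P <- suppressMessages(aalen_johansen(tab, s = s))
    for (j in 0:1) {
      expect_equal(expected_los_given_state(P, j = j, tau = tau),
                   oracle_e(rec, s, j, tau), tolerance = 1e-10)
    }
  }
})
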