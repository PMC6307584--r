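# Brute-force oracles, deliberately independent of the package internals:
# counts are obtained by looping over patients with explicit comparisons and
# transition probabilities by explicit 3x3 matrix products.

make_records <- function(t_int, t_end, discharged = TRUE,
                         cohort = "intervention_era") {
  n <- length(t_end)
  tibble::tibble(
    patient_id = sprintf("p%03d", seq_len(n)),
    cohort = rep_len(cohort, n),
    t_intervention = t_int,
    t_end = t_end,
    discharged = rep_len(discharged, n),
    age = rep_len(70, n),
    sex = rep_len(c("female", "male"), n)
  )
}

# random small cohort with ties (integer days) and occasional censoring
random_cohort <- function(n, seed, p_int = 0.5, p_censor = 0.2, max_day = 12) {
  set.seed(seed)
  t_end <- sample.int(max_day, n, replace = TRUE)
  has_int <- runif(n) < p_int
  t_int <- ifelse(has_int, pmax(1, floor(runif(n) * t_end)), NA_real_)
  t_int <- pmin(t_int, t_end)
  make_records(t_int, t_end, discharged = runif(n) > p_censor)
}

oracle_event_times <- function(rec) {
  sort(unique(c(rec$t_intervention[!is.na(rec$t_intervention)], rec$t_end)))
}

# increment matrix at time u under the tie convention: the 0->1 / 0->2 stage
# (risk set y0 just before u) followed by the 1->2 stage (risk set including
# same-time entrants)
oracle_increment <- function(rec, u) {
  has <- !is.na(rec$t_intervention)
  exit0 <- ifelse(has, rec$t_intervention, rec$t_end)
  y0 <- sum(exit0 >= u)
  d01 <- sum(has & rec$t_intervention == u)
  d02 <- sum(!has & rec$discharged & rec$t_end == u)
  d12 <- sum(has & rec$discharged & rec$t_end == u)
  y1 <- sum(has & rec$t_intervention <= u & rec$t_end >= u)
  A <- diag(3)
  if (y0 > 0) {
    A[1, ] <- c(1 - (d01 + d02) / y0, d01 / y0, d02 / y0)
  }
  B <- diag(3)
  if (y1 > 0) {
    B[2, ] <- c(0, 1 - d12 / y1, d12 / y1)
  }
  A %*% B
}

oracle_P <- function(rec, s, t) {
  us <- oracle_event_times(rec)
  us <- us[us > s & us <= t]
  P <- diag(3)
  for (u in us) P <- P %*% oracle_increment(rec, u)
  P
}

# step-function integral of the in-hospital probability from s to tau
oracle_e <- function(rec, s, j, tau) {
  us <- oracle_event_times(rec)
  grid <- c(s, us[us > s & us < tau])
  inhosp <- vapply(grid, function(u) sum(oracle_P(rec, s, u)[j + 1, 1:2]), numeric(1))
  s + sum(diff(c(grid, tau)) * inhosp)
}

oracle_clos <- function(rec) {
  us <- oracle_event_times(rec)
  tau <- max(us)
  has <- !is.na(rec$t_intervention)
  exit0 <- ifelse(has, rec$t_intervention, rec$t_end)
  d01 <- vapply(us, function(u) sum(has & rec$t_intervention == u), numeric(1))
  y0 <- vapply(us, function(u) sum(exit0 >= u), numeric(1))
  p00_pre <- vapply(us, function(u) oracle_P(rec, 0, max(c(0, us[us < u])))[1, 1], numeric(1))
  dF1 <- ifelse(y0 > 0, p00_pre * d01 / y0, 0)
  w <- dF1 / sum(dF1)
  s_times <- us[d01 > 0]
  phi <- vapply(s_times, function(s) oracle_e(rec, s, 1, tau) - oracle_e(rec, s, 0, tau),
                numeric(1))
  list(delta = sum(phi * w[d01 > 0]), times = s_times, phi = phi,
       weights = w[d01 > 0], tau = tau)
}
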