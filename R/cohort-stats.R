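#' Welch mean difference from group summary statistics
#'
#' Two-sample comparison of means computed directly from summary statistics
#' (mean, SD, n per group), as needed when only published summaries are
#' available. The default uses the unpooled-variance standard error with
#' Welch-Satterthwaite degrees of freedom; `pooled = TRUE` gives the
#' classical equal-variance t-test.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @param level Confidence level.
#' @param pooled Use the pooled-variance test instead of Welch.
#' @return A one-row tibble with `difference` (`mean2 - mean1`), `ci_low`,
#'   `ci_high`, `statistic`, `df`, `p_value`.
#' @export
welch_mean_difference <- function(mean1, sd1, n1, mean2, sd2, n2,
                                  level = 0.95, pooled = FALSE) {
  check_number(mean1, "mean1"); check_number(mean2, "mean2")
  check_number(sd1, "sd1", lower = 0, strict = TRUE)
  check_number(sd2, "sd2", lower = 0, strict = TRUE)
  n1 <- check_count(n1, "n1", lower = 2L)
  n2 <- check_count(n2, "n2", lower = 2L)
  check_number(level, "level", lower = 0, strict = TRUE)
  if (level >= 1) abort_bad_param("`level` must be strictly between 0 and 1.")

  diff <- mean2 - mean1
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  if (pooled) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  stat <- diff / se
  crit <- stats::qt(1 - (1 - level) / 2, df)
  tibble::tibble(
    difference = diff,
    ci_low = diff - crit * se,
    ci_high = diff + crit * se,
    statistic = stat,
    df = df,
    p_value = 2 * stats::pt(-abs(stat), df)
  )
}

#' Chi-squared test for a 2x2 table with continuity correction
#'
#' Yates-corrected chi-squared test on one degree of freedom, the
#' conventional test for a sex-by-cohort table at these sample sizes. The
#' uncorrected statistic is available with `correct = FALSE` and is always at
#' least as large as the corrected one.
#'
#' @param table A 2x2 matrix of counts.
#' @param correct Apply the continuity correction (default).
#' @return A one-row tibble with `statistic`, `df`, `p_value`, `corrected`.
#' @export
yates_chisq <- function(table, correct = TRUE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) || anyNA(table)) {
    abort_bad_param("`table` must be a 2x2 matrix of non-negative counts.")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort_bad_param("every margin of `table` must be positive.")
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = correct))
  tibble::tibble(
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = res$p.value,
    corrected = correct
  )
}

#' Cohort demographics with between-group tests
#'
#' Tabulates per-cohort sample size, mean and SD of age, and the sex split,
#' then compares the cohorts: a Welch t-type comparison of mean age (from the
#' group summaries) and a continuity-corrected chi-squared test of the
#' sex-by-cohort table.
#'
#' @param records A patient tibble (see [validate_patients()]).
#' @param level Confidence level for the age comparison.
#' @return An object of class `cohort_comparison`: list with `summary` (one
#'   row per cohort: `cohort`, `n`, `age_mean`, `age_sd`, `n_female`,
#'   `n_male`), `age_test`, `sex_test`. [tidy()] returns the summary table;
#'   [glance()] a one-row tibble of test results.
#' @export
cohort_summary <- function(records, level = 0.95) {
  records <- validate_patients(records)
  smry <- records |>
    dplyr::group_by(.data$cohort) |>
    dplyr::summarise(
      n = dplyr::n(),
      age_mean = mean(.data$age),
      age_sd = stats::sd(.data$age),
      n_female = sum(.data$sex == "female"),
      n_male = sum(.data$sex == "male"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$cohort)
  age_test <- NULL
  sex_test <- NULL
  if (nrow(smry) == 2 && all(smry$n >= 2)) {
    age_test <- welch_mean_difference(
      smry$age_mean[1], smry$age_sd[1], smry$n[1],
      smry$age_mean[2], smry$age_sd[2], smry$n[2], level = level
    )
    sex_tab <- rbind(smry$n_female, smry$n_male)
    if (all(rowSums(sex_tab) > 0)) sex_test <- yates_chisq(t(sex_tab))
  }
  structure(list(summary = smry, age_test = age_test, sex_test = sex_test,
                 level = level),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat("Cohort demographics\n")
  print(x$summary)
  if (!is.null(x$age_test)) {
    cat(sprintf("Age: difference %.1f years (%d%% CI %.1f to %.1f), p = %.3f\n",
                x$age_test$difference, round(100 * x$level),
                x$age_test$ci_low, x$age_test$ci_high, x$age_test$p_value))
  }
  if (!is.null(x$sex_test)) {
    cat(sprintf("Sex: chi-squared %.2f (1 df, continuity corrected), p = %.2f\n",
                x$sex_test$statistic, x$sex_test$p_value))
  }
  invisible(x)
}

#' @rdname cohort_summary
#' @param x A `cohort_comparison`.
#' @param ... Unused.
#' @method tidy cohort_comparison
#' @export
tidy.cohort_comparison <- function(x, ...) x$summary

#' @rdname cohort_summary
#' @method glance cohort_comparison
#' @export
glance.cohort_comparison <- function(x, ...) {
  tibble::tibble(
    age_difference = x$age_test$difference %||% NA_real_,
    age_ci_low = x$age_test$ci_low %||% NA_real_,
    age_ci_high = x$age_test$ci_high %||% NA_real_,
    age_p_value = x$age_test$p_value %||% NA_real_,
    sex_statistic = x$sex_test$statistic %||% NA_real_,
    sex_p_value = x$sex_test$p_value %||% NA_real_
  )
}
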