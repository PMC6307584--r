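#' Patient-level bootstrap of the change-in-LOS estimate
#'
#' Resamples whole patients with replacement, re-runs [estimate_clos()] on
#' each resample, and summarises the replicate estimates with a percentile
#' confidence interval. Replicates in which the estimand is undefined (the
#' resample contains no intermediate events or no discharges) are dropped and
#' counted in `n_failed` rather than imputed.
#'
#' @param records A patient tibble (see [validate_patients()]).
#' @param B Number of bootstrap replicates (default 1000).
#' @param level Confidence level for the percentile interval.
#' @param seed Integer seed; the replicate stream is deterministic given
#'   `(records, B, seed)`.
#' @param stratify_by_cohort Resample within cohort rather than from the
#'   pooled sample. The default is unstratified pooled resampling.
#' @return An object of class `clos_boot`: list with `estimate` (the
#'   full-sample [estimate_clos()] delta), `replicates` (successful replicate
#'   deltas), `bed_days_released` (their negatives), `ci_low`, `ci_high`,
#'   `level`, `B`, `n_failed`, `seed`. [tidy()] returns the replicates as a
#'   tibble; [glance()] the one-row summary.
#' @export
bootstrap_clos <- function(records, B = 1000, level = 0.95, seed = 1L,
                           stratify_by_cohort = FALSE) {
  records <- validate_patients(records)
  B <- check_count(B, "B")
  check_number(level, "level", lower = 0, strict = TRUE)
  if (level >= 1) abort_bad_param("`level` must be strictly between 0 and 1.")
  seed <- check_count(seed, "seed", lower = 0L)

  full <- estimate_clos(records)
  t_int <- records$t_intervention
  t_end <- records$t_end
  disc <- records$discharged
  n <- length(t_end)
  strata <- if (stratify_by_cohort) split(seq_len(n), records$cohort) else list(seq_len(n))

  reps <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- unlist(lapply(strata, function(ix) ix[sample.int(length(ix), length(ix), replace = TRUE)]),
                    use.names = FALSE)
      tryCatch(
        {
          if (!any(disc[idx])) stop_undefined()
          clos_core(t_int[idx], t_end[idx], disc[idx])$delta
        },
        bedrelease_error_clos_undefined = function(e) NA_real_
      )
    }, numeric(1))
  })
  n_failed <- sum(is.na(reps))
  if (n_failed > B / 2) {
    abort(sprintf(
      paste("Bootstrap inference failed: %d of %d replicates had an undefined estimand.",
            "Larger cohorts (or more intermediate events) are needed."), n_failed, B),
      class = "bedrelease_error_inference")
  }
  ok <- reps[!is.na(reps)]
  alpha <- (1 - level) / 2
  ci <- stats::quantile(ok, probs = c(alpha, 1 - alpha), names = FALSE)
  structure(
    list(estimate = full$delta, replicates = ok, bed_days_released = -ok,
         ci_low = ci[1], ci_high = ci[2], level = level, B = B,
         n_failed = n_failed, seed = seed,
         stratified = stratify_by_cohort),
    class = "clos_boot"
  )
}

stop_undefined <- function() {
  abort("undefined", class = "bedrelease_error_clos_undefined")
}

#' @export
print.clos_boot <- function(x, ...) {
  cat("Bootstrap of the change in expected length of stay\n")
  cat(sprintf("  point estimate: %.2f days (%.2f bed days released per patient)\n",
              x$estimate, -x$estimate))
  cat(sprintf("  %d%% percentile CI: (%.2f, %.2f) days\n",
              round(100 * x$level), x$ci_low, x$ci_high))
  cat(sprintf("  B = %d replicates (%d failed), seed %d\n", x$B, x$n_failed, x$seed))
  invisible(x)
}

#' @rdname bootstrap_clos
#' @param x,object A `clos_boot`.
#' @param ... Unused.
#' @method tidy clos_boot
#' @export
tidy.clos_boot <- function(x, ...) {
  tibble::tibble(replicate_delta = x$replicates,
                 bed_days_released = x$bed_days_released)
}

#' @rdname bootstrap_clos
#' @method glance clos_boot
#' @export
glance.clos_boot <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate, ci_low = x$ci_low, ci_high = x$ci_high,
    level = x$level, B = x$B, n_failed = x$n_failed, seed = x$seed
  )
}

#' Histogram of bed days released per patient
#'
#' Bins the bootstrap draws of bed days released (the negated replicate
#' deltas) into uniform bins spanning the data, the display used to report
#' the skew of the estimate's distribution.
#'
#' @param result A [bootstrap_clos()] result.
#' @param bin_width Bin width in days (> 0).
#' @return A tibble with `bin_left`, `bin_right`, `count`; the counts sum to
#'   the number of successful replicates.
#' @export
histogram_bed_days <- function(result, bin_width = 5) {
  if (!inherits(result, "clos_boot")) {
    abort_bad_param("`result` must be created by bootstrap_clos().")
  }
  check_number(bin_width, "bin_width", lower = 0, strict = TRUE)
  x <- result$bed_days_released
  if (length(x) == 0) abort_bad_param("No successful replicates to bin.")
  lo <- floor(min(x) / bin_width) * bin_width
  idx <- pmin(floor((x - lo) / bin_width), ceiling((max(x) - lo) / bin_width - 1e-9))
  idx <- pmax(idx, 0)
  n_bins <- max(idx) + 1L
  counts <- tabulate(idx + 1L, nbins = n_bins)
  tibble::tibble(
    bin_left = lo + bin_width * (seq_len(n_bins) - 1L),
    bin_right = lo + bin_width * seq_len(n_bins),
    count = counts
  )
}

#' @rdname bootstrap_clos
#' @method autoplot clos_boot
#' @export
autoplot.clos_boot <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$bed_days_released)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = -object$estimate, colour = "firebrick") +
    ggplot2::labs(
      x = "Bed days released per patient",
      y = "Bootstrap replicates",
      title = "Bootstrap distribution of bed days released per patient",
      subtitle = sprintf("%d%% percentile CI for the LOS change: (%.1f, %.1f) days",
                         round(100 * object$level), object$ci_low, object$ci_high)
    ) +
    ggplot2::theme_minimal()
}
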