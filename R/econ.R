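#' Configuration of the Monte Carlo economic model
#'
#' Holds the cost and activity inputs of the economic evaluation: the annual
#' employment costs of the model-of-care team, the number of patients managed
#' per month (uncertain, modelled as uniform), the time horizon, and the
#' decision maker's willingness to pay for one bed day released.
#'
#' Two total-cost figures are carried: the sum of the rounded cost
#' components (by default $158,000 + $71,000 = $229,000) and an exact
#' `total_cost_override` (default $228,876) used in the cost-per-bed-day
#' arithmetic; set the override to `NULL` to use the component sum. Costs are
#' treated as known with certainty and, with a 12-month horizon, are not
#' discounted.
#'
#' @param cost_components Named numeric vector of annual costs (AUD).
#' @param total_cost_override Exact total annual cost (AUD), or `NULL` for
#'   the component sum.
#' @param months Time horizon in months.
#' @param patients_per_month_low,patients_per_month_high Bounds of the
#'   uniform distribution of patients managed per month.
#' @param discrete_patients Draw patients per month from the discrete uniform
#'   on `low:high` instead of the continuous uniform.
#' @param n_sims Number of Monte Carlo simulations.
#' @param wtp Willingness to pay per bed day released (AUD).
#' @param pairing `"resample"` draws bed-days values with replacement from
#'   the supplied draws; `"one_to_one"` consumes them in order (requires
#'   exactly `n_sims` values), preserving a one-to-one pass over bootstrap
#'   replicates.
#' @param seed Integer seed.
#' @return An object of class `econ_config`.
#' @export
econ_config <- function(cost_components = c("specialist social worker" = 158000,
                                            "social work assistant" = 71000),
                        total_cost_override = 228876,
                        months = 12,
                        patients_per_month_low = 20,
                        patients_per_month_high = 30,
                        discrete_patients = FALSE,
                        n_sims = 1000,
                        wtp = 216,
                        pairing = c("resample", "one_to_one"),
                        seed = 1L) {
  if (!is.numeric(cost_components) || length(cost_components) < 1 || any(cost_components < 0)) {
    abort_bad_param("`cost_components` must be a non-empty numeric vector of non-negative costs.")
  }
  if (!is.null(total_cost_override)) check_number(total_cost_override, "total_cost_override", lower = 0)
  months <- check_count(months, "months")
  check_number(patients_per_month_low, "patients_per_month_low", lower = 0)
  check_number(patients_per_month_high, "patients_per_month_high", lower = 0)
  if (patients_per_month_low > patients_per_month_high) {
    abort_bad_param("`patients_per_month_low` must not exceed `patients_per_month_high`.")
  }
  n_sims <- check_count(n_sims, "n_sims")
  check_number(wtp, "wtp", lower = 0)
  pairing <- match.arg(pairing)
  seed <- check_count(seed, "seed", lower = 0L)
  structure(
    list(cost_components = cost_components,
         total_cost_override = total_cost_override,
         months = months,
         patients_per_month_low = patients_per_month_low,
         patients_per_month_high = patients_per_month_high,
         discrete_patients = isTRUE(discrete_patients),
         n_sims = n_sims, wtp = wtp, pairing = pairing, seed = seed),
    class = "econ_config"
  )
}

#' Total annual cost implied by an economic configuration
#'
#' @param config An [econ_config()].
#' @return The override if set, otherwise the sum of the cost components.
#' @export
total_cost <- function(config) {
  if (!inherits(config, "econ_config")) abort_bad_param("`config` must be an econ_config().")
  config$total_cost_override %||% sum(config$cost_components)
}

#' Monte Carlo simulation of annual bed days released and cost per bed day
#'
#' Each simulation independently draws `b`, the bed days released per patient
#' managed (sampled with replacement from `bed_day_draws`, typically the
#' bootstrap distribution of [bootstrap_clos()]), and `m`, the patients
#' managed per month (uniform between the configured bounds), and computes
#' annual bed days released `b * m * months` and the cost per bed day
#' released `total_cost / (b * m * months)`.
#'
#' Simulations with `b <= 0` release no bed days: their cost per bed day is
#' undefined, they are excluded from cost summaries, and they count as not
#' meeting any willingness-to-pay criterion.
#'
#' @param bed_day_draws Numeric vector of bed-days-released-per-patient
#'   values, e.g. `bootstrap_clos(...)$bed_days_released`.
#' @param config An [econ_config()].
#' @return An object of class `econ_sim`: list with `sims` (tibble of
#'   `bed_days_per_patient`, `patients_per_month`, `annual_bed_days`,
#'   `cost_per_bed_day`), `total_cost`, `component_cost` (sum of components),
#'   `p_meets_wtp` (fraction of all simulations with cost per bed day below
#'   the willingness to pay), `n_nonpositive`, and the config. [tidy()]
#'   returns a summary table (mean, SD, min, max per quantity); [glance()]
#'   the headline scalars.
#' @export
run_monte_carlo <- function(bed_day_draws, config = econ_config()) {
  if (!inherits(config, "econ_config")) abort_bad_param("`config` must be an econ_config().")
  if (!is.numeric(bed_day_draws) || length(bed_day_draws) == 0 || anyNA(bed_day_draws)) {
    abort_bad_param("`bed_day_draws` must be a non-empty numeric vector without NAs.")
  }
  if (all(bed_day_draws <= 0)) {
    abort("Economic evaluation is undefined: every bed-days draw is non-positive.",
          class = "bedrelease_error_econ_undefined")
  }
  n <- config$n_sims
  if (config$pairing == "one_to_one" && length(bed_day_draws) != n) {
    abort_bad_param("one_to_one pairing requires length(bed_day_draws) == n_sims.")
  }
  cost <- total_cost(config)
  sims <- withr::with_seed(config$seed, {
    b <- if (config$pairing == "one_to_one") as.numeric(bed_day_draws)
         else sample(bed_day_draws, n, replace = TRUE)
    m <- if (config$discrete_patients) {
      sample(seq(config$patients_per_month_low, config$patients_per_month_high),
             n, replace = TRUE)
    } else {
      stats::runif(n, config$patients_per_month_low, config$patients_per_month_high)
    }
    tibble::tibble(bed_days_per_patient = b, patients_per_month = m)
  })
  sims$annual_bed_days <- sims$bed_days_per_patient * sims$patients_per_month * config$months
  sims$cost_per_bed_day <- ifelse(sims$bed_days_per_patient > 0,
                                  cost / sims$annual_bed_days, NA_real_)
  n_nonpositive <- sum(sims$bed_days_per_patient <= 0)
  p_meets <- mean(!is.na(sims$cost_per_bed_day) & sims$cost_per_bed_day < config$wtp)
  structure(
    list(sims = sims, total_cost = cost,
         component_cost = sum(config$cost_components),
         p_meets_wtp = p_meets, n_nonpositive = n_nonpositive,
         config = config),
    class = "econ_sim"
  )
}

#' @export
print.econ_sim <- function(x, ...) {
  cat("Monte Carlo economic evaluation\n")
  cat(sprintf("  total annual cost: $%s (component sum $%s)\n",
              format(x$total_cost, big.mark = ","),
              format(x$component_cost, big.mark = ",")))
  cat(sprintf("  simulations: %d (%d released no bed days)\n",
              x$config$n_sims, x$n_nonpositive))
  usable <- x$sims[x$sims$bed_days_per_patient > 0, ]
  cat(sprintf("  mean annual bed days released: %.0f; mean cost per bed day: $%.0f\n",
              mean(usable$annual_bed_days), mean(usable$cost_per_bed_day)))
  cat(sprintf("  P(cost per bed day < $%s) = %.3f\n", x$config$wtp, x$p_meets_wtp))
  invisible(x)
}

#' Summary table of a Monte Carlo economic evaluation
#'
#' One row per simulated quantity with mean, SD, minimum and maximum, the
#' standard reporting layout for probabilistic models of this kind. Cost
#' rows are computed over the simulations that released bed days.
#'
#' @param x,object An `econ_sim`.
#' @param rounded Round bed days to whole days, patients to whole patients
#'   and costs to whole dollars for a human-readable table; the default keeps
#'   full precision.
#' @param ... Unused.
#' @return A tibble with `quantity`, `mean`, `sd`, `min`, `max`.
#' @method tidy econ_sim
#' @export
tidy.econ_sim <- function(x, rounded = FALSE, ...) {
  usable <- x$sims[x$sims$bed_days_per_patient > 0, ]
  row <- function(v) c(mean(v), stats::sd(v), min(v), max(v))
  out <- tibble::tibble(
    quantity = c("bed_days_per_patient", "patients_per_month",
                 "annual_bed_days", "cost_per_bed_day"),
    as.data.frame(rbind(
      row(x$sims$bed_days_per_patient),
      row(x$sims$patients_per_month),
      row(usable$annual_bed_days),
      row(usable$cost_per_bed_day)
    ))
  )
  names(out)[2:5] <- c("mean", "sd", "min", "max")
  if (rounded) out <- dplyr::mutate(out, dplyr::across(c("mean", "sd", "min", "max"), round))
  out
}

#' @rdname tidy.econ_sim
#' @method glance econ_sim
#' @export
glance.econ_sim <- function(x, ...) {
  tibble::tibble(
    total_cost = x$total_cost,
    component_cost = x$component_cost,
    p_meets_wtp = x$p_meets_wtp,
    wtp = x$config$wtp,
    n_sims = x$config$n_sims,
    n_nonpositive = x$n_nonpositive
  )
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value on a grid, the probability (fraction of
#' simulations) that the cost per bed day released falls below it.
#' Simulations that released no bed days never meet the criterion. The curve
#' is non-decreasing in the threshold by construction.
#'
#' @param result An [run_monte_carlo()] result.
#' @param wtp_grid Numeric vector of willingness-to-pay thresholds (AUD).
#' @return A tibble of class `ceac_curve` with `wtp` and `probability`.
#' @export
ceac <- function(result, wtp_grid = seq(0, 300, by = 5)) {
  if (!inherits(result, "econ_sim")) abort_bad_param("`result` must be created by run_monte_carlo().")
  if (!is.numeric(wtp_grid) || length(wtp_grid) == 0) {
    abort_bad_param("`wtp_grid` must be a non-empty numeric vector.")
  }
  cpd <- result$sims$cost_per_bed_day
  n <- nrow(result$sims)
  prob <- vapply(sort(wtp_grid),
                 function(w) sum(!is.na(cpd) & cpd < w) / n, numeric(1))
  out <- tibble::tibble(wtp = sort(wtp_grid), probability = prob)
  class(out) <- c("ceac_curve", class(out))
  out
}

#' @method autoplot ceac_curve
#' @export
autoplot.ceac_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wtp, y = .data$probability)) +
    ggplot2::geom_step(colour = "steelblue", linewidth = 0.8) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Willingness to pay per bed day released (AUD)",
      y = "Probability cost per bed day is below threshold",
      title = "Cost-effectiveness acceptability curve"
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot econ_sim
#' @export
autoplot.econ_sim <- function(object, ...) {
  usable <- object$sims[object$sims$bed_days_per_patient > 0, ]
  ggplot2::ggplot(usable, ggplot2::aes(x = .data$cost_per_bed_day)) +
    ggplot2::geom_histogram(bins = 30, fill = "darkseagreen4", colour = "white") +
    ggplot2::geom_vline(xintercept = object$config$wtp, colour = "firebrick",
                        linetype = "dashed") +
    ggplot2::labs(
      x = "Cost per bed day released (AUD)",
      y = "Simulations",
      title = "Monte Carlo distribution of the cost per bed day released",
      subtitle = sprintf("Dashed line: willingness to pay $%s; P(below) = %.2f",
                         object$config$wtp, object$p_meets_wtp)
    ) +
    ggplot2::theme_minimal()
}
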