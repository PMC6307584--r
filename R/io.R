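#' Read patient event histories from CSV
#'
#' Expects a header row with columns `patient_id, cohort, t_intervention,
#' t_end, discharged, age, sex`; times are durations in days from admission.
#' A blank `t_intervention` marks a patient who never entered the
#' intermediate state. Lines starting with `#` are treated as comments (the
#' package's own writers put provenance there). All validation failures are
#' collected and reported together with their row numbers.
#'
#' @param path Path to a CSV file.
#' @return A validated patient tibble (see [validate_patients()]).
#' @export
read_patients <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("Input file not found: %s", path))
  # column mismatches surface through validate_patients, not readr warnings
  raw <- suppressWarnings(readr::read_csv(
    path, comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      cohort = readr::col_character(),
      t_intervention = readr::col_double(),
      t_end = readr::col_double(),
      discharged = readr::col_logical(),
      age = readr::col_double(),
      sex = readr::col_character()
    )
  ))
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    abort_validation(c(
      sprintf("Malformed values in %s.", path),
      sprintf("row %d, column %s: expected %s, got '%s'",
              prob$row, prob$col, prob$expected, prob$actual)
    ))
  }
  validate_patients(raw)
}

#' Write patient event histories to CSV
#'
#' Writes the standard patient CSV schema with a `# seed=... generator=...`
#' provenance comment line when a scenario is supplied, plus a JSON sidecar
#' (`<path>.scenario.json`) recording the generating scenario.
#'
#' @param records A patient tibble.
#' @param path Output CSV path.
#' @param scenario Optional generating scenario ([markov_scenario()] or
#'   [study_scenario()]) recorded for provenance.
#' @return `path`, invisibly.
#' @export
write_patients <- function(records, path, scenario = NULL) {
  records <- validate_patients(records)
  lines <- character(0)
  if (!is.null(scenario)) {
    lines <- sprintf("# generator=%s seed=%s", class(scenario)[1], scenario$seed)
    jsonlite::write_json(unclass(scenario), paste0(path, ".scenario.json"),
                         auto_unbox = TRUE, null = "null", digits = NA, pretty = TRUE)
  }
  body <- readr::format_csv(records)
  writeLines(c(lines, sub("\n$", "", body)), path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: where the patient records come
#' from (a CSV path or an in-memory tibble), where outputs go, the bootstrap
#' settings and the economic model configuration.
#'
#' @param input Path to a patient CSV (see [read_patients()]), or `NULL` when
#'   `records` is given.
#' @param records A patient tibble, alternative to `input`.
#' @param output_dir Directory for all outputs (created if missing).
#' @param seed Integer master seed; the bootstrap and the economic simulation
#'   derive their streams from it and every output records it.
#' @param bootstrap_B Bootstrap replicates.
#' @param level Confidence level.
#' @param stratify_by_cohort Stratify the bootstrap by cohort.
#' @param econ An [econ_config()]; its `seed` is replaced by `seed + 1` so
#'   one master seed drives the whole pipeline.
#' @param bin_width Bin width (days) of the bed-days histogram output.
#' @param wtp_grid Willingness-to-pay grid for the CEAC output.
#' @param verbose Emit progress messages.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = NULL, records = NULL, output_dir = tempfile("bedrelease_run_"),
                       seed = 1L, bootstrap_B = 1000, level = 0.95,
                       stratify_by_cohort = FALSE, econ = econ_config(),
                       bin_width = 5, wtp_grid = seq(0, 300, by = 5),
                       verbose = TRUE) {
  if (is.null(input) && is.null(records)) {
    abort_bad_param("Provide either `input` (a CSV path) or `records` (a tibble).")
  }
  seed <- check_count(seed, "seed", lower = 0L)
  bootstrap_B <- check_count(bootstrap_B, "bootstrap_B")
  if (!inherits(econ, "econ_config")) abort_bad_param("`econ` must be an econ_config().")
  econ$seed <- seed + 1L
  structure(
    list(input = input, records = records, output_dir = output_dir,
         seed = seed, bootstrap_B = bootstrap_B, level = level,
         stratify_by_cohort = stratify_by_cohort, econ = econ,
         bin_width = bin_width, wtp_grid = wtp_grid, verbose = verbose),
    class = "run_config"
  )
}

config_hash <- function(config) {
  stable <- config[setdiff(names(config), c("records", "verbose", "output_dir"))]
  rlang::hash(stable)
}

write_stamped_csv <- function(df, path, seed, hash) {
  body <- readr::format_csv(df)
  writeLines(c(sprintf("# seed=%s config=%s", seed, hash), sub("\n$", "", body)), path)
  path
}

#' Run the full length-of-stay evaluation pipeline
#'
#' Executes the end-to-end analysis: cohort demographics, the multistate
#' change-in-LOS estimate, the patient-level bootstrap, and the Monte Carlo
#' economic evaluation, writing every result to `config$output_dir`:
#'
#' * `clos.json` — the change-in-LOS estimate with its phi/weight curves;
#' * `bootstrap_replicates.csv`, `bootstrap_summary.json`,
#'   `histogram_bed_days.csv`;
#' * `econ_summary.csv`, `econ_summary.json`, `ceac.csv`;
#' * `cohort_summary.csv`, `cohort_tests.json`;
#' * `manifest.json` — configuration, seed, config hash, package and R
#'   versions, per-stage timings and headline numbers.
#'
#' Every CSV carries a `# seed=... config=...` comment line and every JSON a
#' `seed`/`config_hash` field, so a run can be reproduced from any one of its
#' outputs. A failure in any stage aborts with the stage name after writing a
#' partial manifest.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the fitted objects (`clos`, `boot`, `econ`,
#'   `cohort`), the output `paths`, and the `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) abort_bad_param("`config` must be created by run_config().")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  say <- function(...) if (isTRUE(config$verbose)) inform(sprintf(...))
  timings <- list()
  stamp <- list(seed = config$seed, config_hash = hash)
  manifest_path <- file.path(config$output_dir, "manifest.json")
  results <- list()
  paths <- list()

  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fun(), error = function(e) {
      partial <- c(stamp, list(
        status = "failed", failed_stage = name, error = conditionMessage(e),
        completed_stages = names(timings)
      ))
      jsonlite::write_json(partial, manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "bedrelease_error_pipeline", parent = e)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  records <- stage("read", function() {
    if (!is.null(config$records)) validate_patients(config$records)
    else read_patients(config$input)
  })
  say("Loaded %d patients.", nrow(records))

  results$cohort <- stage("cohort_summary", function() cohort_summary(records, config$level))
  paths$cohort_summary <- write_stamped_csv(
    tidy(results$cohort), file.path(config$output_dir, "cohort_summary.csv"),
    config$seed, hash)
  jsonlite::write_json(c(stamp, as.list(glance(results$cohort))),
                       file.path(config$output_dir, "cohort_tests.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  results$clos <- stage("estimate", function() estimate_clos(records))
  say("Change in expected LOS: %.2f days.", results$clos$delta)
  paths$clos <- file.path(config$output_dir, "clos.json")
  jsonlite::write_json(c(stamp, list(
    delta = results$clos$delta,
    bed_days_released = -results$clos$delta,
    tau = results$clos$tau,
    n_patients = results$clos$n_patients,
    phi_times = results$clos$curve$time,
    phi = results$clos$curve$phi,
    weights = results$clos$curve$weight
  )), paths$clos, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  results$boot <- stage("bootstrap", function() {
    bootstrap_clos(records, B = config$bootstrap_B, level = config$level,
                   seed = config$seed, stratify_by_cohort = config$stratify_by_cohort)
  })
  say("Bootstrap: %d%% CI (%.2f, %.2f) days, %d failed replicates.",
      round(100 * config$level), results$boot$ci_low, results$boot$ci_high,
      results$boot$n_failed)
  paths$replicates <- write_stamped_csv(
    tidy(results$boot), file.path(config$output_dir, "bootstrap_replicates.csv"),
    config$seed, hash)
  jsonlite::write_json(c(stamp, as.list(glance(results$boot))),
                       file.path(config$output_dir, "bootstrap_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths$histogram <- write_stamped_csv(
    histogram_bed_days(results$boot, config$bin_width),
    file.path(config$output_dir, "histogram_bed_days.csv"), config$seed, hash)

  results$econ <- stage("econ", function() {
    run_monte_carlo(results$boot$bed_days_released, config$econ)
  })
  say("Economic model: P(cost per bed day < $%s) = %.3f.",
      config$econ$wtp, results$econ$p_meets_wtp)
  paths$econ_summary <- write_stamped_csv(
    tidy(results$econ), file.path(config$output_dir, "econ_summary.csv"),
    config$seed, hash)
  jsonlite::write_json(c(stamp, as.list(glance(results$econ))),
                       file.path(config$output_dir, "econ_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$ceac <- stage("ceac", function() ceac(results$econ, config$wtp_grid))
  paths$ceac <- write_stamped_csv(
    results$ceac, file.path(config$output_dir, "ceac.csv"), config$seed, hash)

  manifest <- c(stamp, list(
    status = "complete",
    package_version = as.character(utils::packageVersion("bedrelease")),
    r_version = as.character(getRversion()),
    config = list(
      input = config$input %||% "(in-memory records)",
      bootstrap_B = config$bootstrap_B, level = config$level,
      stratify_by_cohort = config$stratify_by_cohort,
      bin_width = config$bin_width,
      econ = unclass(config$econ)
    ),
    n_patients = nrow(records),
    delta = results$clos$delta,
    bed_days_released = -results$clos$delta,
    ci_low = results$boot$ci_low, ci_high = results$boot$ci_high,
    p_meets_wtp = results$econ$p_meets_wtp,
    timings_sec = timings
  ))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths$manifest <- manifest_path
  say("Pipeline complete; outputs in %s", config$output_dir)
  invisible(list(clos = results$clos, boot = results$boot, econ = results$econ,
                 ceac = results$ceac, cohort = results$cohort,
                 paths = paths, manifest = manifest))
}
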