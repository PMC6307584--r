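#' Validate a patient event-history table
#'
#' Checks that a data frame of patient records satisfies the event-history
#' contract used throughout the package and returns it as a normalised
#' tibble. One row is one patient; times are days from hospital admission.
#'
#' Required columns:
#' \describe{
#'   \item{patient_id}{unique identifier (coerced to character)}
#'   \item{cohort}{`"control"` or `"intervention_era"`}
#'   \item{t_intervention}{days from admission to the intermediate event
#'     (entry into the model of care); `NA` if the patient never enters it}
#'   \item{t_end}{days from admission to discharge or censoring}
#'   \item{discharged}{`TRUE` for an observed discharge, `FALSE` for
#'     censoring}
#'   \item{age}{years}
#'   \item{sex}{`"female"` or `"male"`}
#' }
#'
#' Row-level invariants: `t_end > 0`; when present,
#' `0 < t_intervention <= t_end`; control patients never have
#' `t_intervention`. All violations are collected and reported together,
#' each citing the row number and patient id.
#'
#' @param records A data frame of patient records.
#' @return A validated tibble with the columns above.
#' @export
validate_patients <- function(records) {
  if (!is.data.frame(records)) {
    abort_validation("`records` must be a data frame of patient event histories.")
  }
  required <- c("patient_id", "cohort", "t_intervention", "t_end",
                "discharged", "age", "sex")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort_validation(sprintf("`records` is missing required column(s): %s.",
                             paste(missing_cols, collapse = ", ")))
  }
  if (nrow(records) == 0) {
    abort_validation("`records` contains no patients.")
  }

  out <- tibble::as_tibble(records[required])
  out$patient_id <- as.character(out$patient_id)
  out$cohort <- as.character(out$cohort)
  out$sex <- as.character(out$sex)
  out$t_intervention <- as.numeric(out$t_intervention)
  out$t_end <- as.numeric(out$t_end)
  out$discharged <- as.logical(out$discharged)
  out$age <- as.numeric(out$age)

  problems <- character(0)
  note <- function(rows, msg) {
    if (any(rows)) {
      ids <- paste0("row ", which(rows), " (patient ", out$patient_id[rows], ")")
      problems <<- c(problems, paste0(msg, ": ", paste(ids, collapse = "; ")))
    }
  }

  note(is.na(out$patient_id) | out$patient_id == "", "blank patient_id")
  note(duplicated(out$patient_id) & !is.na(out$patient_id), "duplicated patient_id")
  note(!out$cohort %in% c("control", "intervention_era"),
       "cohort must be 'control' or 'intervention_era'")
  note(!out$sex %in% c("female", "male"), "sex must be 'female' or 'male'")
  note(is.na(out$t_end) | out$t_end <= 0, "t_end must be a positive number of days")
  note(is.na(out$discharged), "discharged must be TRUE or FALSE")
  has_int <- !is.na(out$t_intervention)
  note(has_int & out$t_intervention <= 0, "t_intervention must be positive when present")
  note(has_int & !is.na(out$t_end) & out$t_intervention > out$t_end,
       "t_intervention exceeds t_end")
  note(has_int & out$cohort == "control", "control patients cannot have t_intervention")

  if (length(problems) > 0) {
    abort_validation(c("Invalid patient records.", problems))
  }
  out
}
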