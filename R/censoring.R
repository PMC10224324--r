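#' Determine a patient's censoring date
#'
#' The censoring date is the date up to which the record is screened. It is
#' the run date unless the patient carries an "ambiguous" diagnosis — a
#' condition that can either be a PAD complication or itself cause secondary
#' antibody deficiency (lymphomas, gastric or colorectal cancer,
#' post-transplantation). In that case the record is screened only up to the
#' earliest such diagnosis, and that date becomes the censoring date.
#'
#' @param record A [patient_record()].
#' @param run_date The screening run date (`Date` or ISO string).
#' @param ruleset A `pad_ruleset`.
#' @return A `pad_censored` object: `record`, `censoring_date`, `censored_by`
#'   (`"run_date"` or `"ambiguous_diagnosis"`), `ambiguous_code`.
#' @export
determine_censoring_date <- function(record, run_date, ruleset = default_ruleset()) {
  run_date <- as_date_strict(run_date, "run_date")
  dx <- record$diagnoses
  amb <- dx[dx$icpc_code %in% ruleset$ambiguous$icpc_code & dx$date <= run_date, ]
  if (nrow(amb) > 0) {
    i <- which.min(amb$date)
    out <- list(record = record, censoring_date = amb$date[i],
                censored_by = "ambiguous_diagnosis",
                ambiguous_code = amb$icpc_code[i])
  } else {
    out <- list(record = record, censoring_date = run_date,
                censored_by = "run_date", ambiguous_code = NA_character_)
  }
  structure(out, class = "pad_censored")
}

#' Check screening eligibility
#'
#' A patient is excluded from screening if any exclusion ICPC code — markers
#' of secondary antibody deficiency or of conditions that mimic the score's
#' components (leukemia, multiple myeloma, HIV/AIDS, substance abuse, eating
#' disorders, a pre-existing immunodeficiency code, cystic fibrosis) — appears
#' anywhere in the record, at any date, or if the patient's age at the
#' censoring date is below 12 or above 70 years. Exclusion codes are screened
#' on the full, untruncated record: an exclusion diagnosis after an
#' ambiguous-diagnosis censoring date still excludes.
#'
#' @param record A [patient_record()].
#' @param censored A `pad_censored` from [determine_censoring_date()].
#' @param ruleset A `pad_ruleset`.
#' @return A list (`pad_eligibility`): `eligible` (logical), `reason`
#'   (`"ok"`, `"age_below_min"`, `"age_above_max"`, `"exclusion_code"`),
#'   `triggering_code` (the first matching exclusion code, or `NA`).
#' @export
check_eligibility <- function(record, censored, ruleset = default_ruleset()) {
  res <- function(eligible, reason, code = NA_character_) {
    structure(list(eligible = eligible, reason = reason, triggering_code = code),
              class = "pad_eligibility")
  }
  hit <- record$diagnoses$icpc_code[
    record$diagnoses$icpc_code %in% ruleset$exclusions$icpc_code]
  if (length(hit) > 0) return(res(FALSE, "exclusion_code", hit[1]))
  age <- age_at(record$birth_date, censored$censoring_date)
  if (age < ruleset$age_min) return(res(FALSE, "age_below_min"))
  if (age > ruleset$age_max) return(res(FALSE, "age_above_max"))
  res(TRUE, "ok")
}

#' Truncate a record at its censoring date
#'
#' Returns a copy of the record in which every event stream retains only
#' events dated on or before the censoring date. Events on the censoring date
#' itself are kept, so an ambiguous code that is also a scored component
#' (e.g. the lymphoma codes) still contributes its own weight.
#'
#' @param record A [patient_record()].
#' @param censored A `pad_censored` from [determine_censoring_date()].
#' @return A truncated `pad_record`.
#' @export
truncate_record <- function(record, censored) {
  cd <- censored$censoring_date
  out <- record
  for (stream in c("diagnoses", "prescriptions", "labs", "visits")) {
    s <- out[[stream]]
    out[[stream]] <- s[s$date <= cd, , drop = FALSE]
  }
  out
}
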