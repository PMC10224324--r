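#' Construct a patient record
#'
#' A `pad_record` holds one patient's structured primary-care history:
#' demographics, the enrollment interval at the GP practice, and four event
#' streams (coded diagnoses, prescriptions, laboratory results, visits).
#' Event streams are stored sorted ascending by date.
#'
#' @param patient_id Opaque identifier string.
#' @param birth_date,enrollment_start Dates (ISO-8601 strings accepted).
#' @param enrollment_end Date, or `NA` for an open (ongoing) enrollment.
#' @param sex `"F"`, `"M"` or `"unknown"`.
#' @param diagnoses Data frame with columns `icpc_code`, `date`.
#' @param prescriptions Data frame with columns `atc_code`, `date`.
#' @param labs Data frame with columns `analyte`, `value`, `date`
#'   (value in g/L).
#' @param visits Data frame with columns `date`, `modality`
#'   (`"physical"` or `"electronic"`).
#' @return A `pad_record`.
#' @export
patient_record <- function(patient_id, birth_date, sex = "unknown",
                           enrollment_start, enrollment_end = NA,
                           diagnoses = NULL, prescriptions = NULL,
                           labs = NULL, visits = NULL) {
  birth_date <- as_date_strict(birth_date, "birth_date")
  enrollment_start <- as_date_strict(enrollment_start, "enrollment_start")
  enrollment_end <- if (length(enrollment_end) == 1 && is.na(enrollment_end)) {
    as.Date(NA)
  } else {
    as_date_strict(enrollment_end, "enrollment_end")
  }
  sex <- match.arg(sex, c("F", "M", "unknown"))

  empty <- function(...) {
    cols <- list(...)
    tibble::as_tibble(cols)
  }
  diagnoses <- if (is.null(diagnoses)) {
    empty(icpc_code = character(), date = as.Date(character()))
  } else {
    tibble::as_tibble(diagnoses)
  }
  prescriptions <- if (is.null(prescriptions)) {
    empty(atc_code = character(), date = as.Date(character()))
  } else {
    tibble::as_tibble(prescriptions)
  }
  labs <- if (is.null(labs)) {
    empty(analyte = character(), value = numeric(), date = as.Date(character()))
  } else {
    tibble::as_tibble(labs)
  }
  visits <- if (is.null(visits)) {
    empty(date = as.Date(character()), modality = character())
  } else {
    tibble::as_tibble(visits)
  }

  diagnoses$icpc_code <- normalize_icpc(diagnoses$icpc_code)
  diagnoses$date <- as_date_strict(diagnoses$date, "diagnosis date")
  prescriptions$atc_code <- normalize_atc(prescriptions$atc_code)
  prescriptions$date <- as_date_strict(prescriptions$date, "prescription date")
  labs$date <- as_date_strict(labs$date, "lab date")
  labs$value <- as.numeric(labs$value)
  labs <- derive_calculated_globulin(labs)
  visits$date <- as_date_strict(visits$date, "visit date")
  visits$modality <- ifelse(visits$modality == "telephone", "electronic",
                            visits$modality)

  by_date <- function(df) df[order(df$date), , drop = FALSE]
  rec <- structure(list(
    patient_id = as.character(patient_id),
    birth_date = birth_date,
    sex = sex,
    enrollment_start = enrollment_start,
    enrollment_end = enrollment_end,
    diagnoses = by_date(diagnoses),
    prescriptions = by_date(prescriptions),
    labs = by_date(labs),
    visits = by_date(visits)
  ), class = "pad_record")
  validate_record(rec)
}

validate_record <- function(rec) {
  if (!is.na(rec$enrollment_end) && rec$enrollment_start > rec$enrollment_end) {
    abort(paste0("Patient ", rec$patient_id,
                 ": enrollment_start after enrollment_end"))
  }
  for (stream in c("diagnoses", "prescriptions", "labs", "visits")) {
    d <- rec[[stream]]$date
    if (length(d) > 0 && any(d < rec$birth_date)) {
      abort(paste0("Patient ", rec$patient_id, ": ", stream,
                   " event before birth_date"))
    }
  }
  bad_mod <- setdiff(unique(rec$visits$modality), c("physical", "electronic"))
  if (length(bad_mod) > 0) {
    abort(paste0("Patient ", rec$patient_id, ": unknown visit modality: ",
                 paste(bad_mod, collapse = ", ")))
  }
  bad_an <- setdiff(unique(rec$labs$analyte), lab_analytes())
  if (length(bad_an) > 0) {
    abort(paste0("Patient ", rec$patient_id, ": unknown analyte: ",
                 paste(bad_an, collapse = ", ")))
  }
  if (length(rec$labs$value) > 0 && any(rec$labs$value < 0, na.rm = TRUE)) {
    abort(paste0("Patient ", rec$patient_id, ": negative lab value"))
  }
  invisible(rec)
}

#' @export
print.pad_record <- function(x, ...) {
  cat("<pad_record>", x$patient_id, "\n")
  cat("  born", format(x$birth_date), "sex", x$sex, "\n")
  cat("  enrolled", format(x$enrollment_start), "to",
      if (is.na(x$enrollment_end)) "(open)" else format(x$enrollment_end), "\n")
  cat(sprintf("  events: %d diagnoses, %d prescriptions, %d labs, %d visits\n",
              nrow(x$diagnoses), nrow(x$prescriptions), nrow(x$labs),
              nrow(x$visits)))
  invisible(x)
}

#' Calculated globulin from total protein and albumin
#'
#' Calculated globulin (g/L) = total protein - albumin; an inexpensive proxy
#' marker for hypogammaglobulinemia available from routine chemistry panels.
#' A result below 18 g/L scores in the default rule set.
#'
#' @param total_protein,albumin Numeric vectors in g/L, both non-negative.
#' @return `total_protein - albumin` (g/L). Values where albumin exceeds
#'   total protein are returned as-is but trigger a data-quality warning
#'   (negative globulin is physiologically impossible).
#' @export
#' @examples
#' compute_calculated_globulin(70, 45)  # 25
compute_calculated_globulin <- function(total_protein, albumin) {
  if (any(total_protein < 0, na.rm = TRUE) || any(albumin < 0, na.rm = TRUE)) {
    abort("total_protein and albumin must be non-negative")
  }
  out <- total_protein - albumin
  if (any(out < 0, na.rm = TRUE)) {
    warn("albumin exceeds total protein for some results: negative calculated globulin is physiologically impossible; check the input data")
  }
  out
}

cohort_table_schemas <- list(
  patients = c("patient_id", "birth_date", "sex", "enrollment_start",
               "enrollment_end"),
  diagnoses = c("patient_id", "icpc_code", "date"),
  prescriptions = c("patient_id", "atc_code", "date"),
  labs = c("patient_id", "analyte", "value_g_per_l", "date"),
  visits = c("patient_id", "date", "modality")
)

read_cohort_table <- function(path, table) {
  if (!file.exists(path)) abort(paste0("Missing cohort table file: ", path))
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  missing <- setdiff(cohort_table_schemas[[table]], names(df))
  if (length(missing) > 0) {
    abort(paste0("Table '", table, "' (", path, ") is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  df
}

#' Load a cohort from five delimited-text tables
#'
#' Reads the comma-separated tables `patients`, `diagnoses`, `prescriptions`,
#' `labs` and `visits` (UTF-8, header row) and assembles one [patient_record()]
#' per patient, with event streams attached, codes normalized (trimmed,
#' upper-cased), and events sorted by date. Telephone consultations are mapped
#' to modality `"electronic"` at load time. Where a `total_protein` and an
#' `albumin` result share a date and no stored `calculated_globulin` result
#' exists on that date, a derived calculated-globulin result is appended.
#'
#' @param paths Named character vector or list mapping the five table names to
#'   file paths; alternatively a single directory containing
#'   `patients.csv`, `diagnoses.csv`, `prescriptions.csv`, `labs.csv`,
#'   `visits.csv`.
#' @return A named list of `pad_record`s (class `pad_cohort`), one per row of
#'   the patients table, in patients-table order.
#' @export
load_cohort <- function(paths) {
  tables <- names(cohort_table_schemas)
  if (is.character(paths) && length(paths) == 1 && dir.exists(paths)) {
    paths <- setNames(file.path(paths, paste0(tables, ".csv")), tables)
  }
  missing <- setdiff(tables, names(paths))
  if (length(missing) > 0) {
    abort(paste0("paths must name all five tables; missing: ",
                 paste(missing, collapse = ", ")))
  }
  raw <- lapply(setNames(tables, tables),
                function(tb) read_cohort_table(paths[[tb]], tb))

  pat_ids <- raw$patients$patient_id
  if (anyDuplicated(pat_ids)) {
    abort(paste0("Duplicate patient_id in patients table: ",
                 paste(unique(pat_ids[duplicated(pat_ids)]), collapse = ", ")))
  }
  for (tb in setdiff(tables, "patients")) {
    orphans <- setdiff(unique(raw[[tb]]$patient_id), pat_ids)
    if (length(orphans) > 0) {
      abort(paste0("Table '", tb, "' has event rows for patient_id(s) absent ",
                   "from the patients table: ", paste(orphans, collapse = ", ")))
    }
  }

  split_by_patient <- function(df) split(df, factor(df$patient_id, levels = pat_ids))
  dx <- split_by_patient(raw$diagnoses)
  rx <- split_by_patient(raw$prescriptions)
  lb <- split_by_patient(raw$labs)
  vs <- split_by_patient(raw$visits)

  records <- lapply(seq_along(pat_ids), function(i) {
    p <- raw$patients[i, ]
    labs_i <- lb[[i]]
    labs_tbl <- tibble::tibble(
      analyte = labs_i$analyte,
      value = as.numeric(labs_i$value_g_per_l),
      date = as_date_strict(labs_i$date, paste0("labs for patient ", p$patient_id))
    )
    patient_record(
      patient_id = p$patient_id,
      birth_date = p$birth_date,
      sex = if (is.na(p$sex) || p$sex == "") "unknown" else p$sex,
      enrollment_start = p$enrollment_start,
      enrollment_end = if (is.na(p$enrollment_end) || p$enrollment_end == "") NA
                       else p$enrollment_end,
      diagnoses = dx[[i]][c("icpc_code", "date")],
      prescriptions = rx[[i]][c("atc_code", "date")],
      labs = labs_tbl,
      visits = vs[[i]][c("date", "modality")]
    )
  })
  structure(setNames(records, pat_ids), class = "pad_cohort")
}

# Append derived calculated-globulin results where total_protein and albumin
# share a date and no stored calculated_globulin result exists on that date.
derive_calculated_globulin <- function(labs) {
  if (nrow(labs) == 0) return(labs)
  tp <- labs[labs$analyte == "total_protein", ]
  alb <- labs[labs$analyte == "albumin", ]
  if (nrow(tp) == 0 || nrow(alb) == 0) return(labs)
  shared <- intersect(as.numeric(tp$date), as.numeric(alb$date))
  have_cg <- as.numeric(labs$date[labs$analyte == "calculated_globulin"])
  shared <- setdiff(shared, have_cg)
  if (length(shared) == 0) return(labs)
  derived <- purrr::map_dfr(shared, function(d) {
    tibble::tibble(
      analyte = "calculated_globulin",
      value = compute_calculated_globulin(
        tp$value[match(d, as.numeric(tp$date))],
        alb$value[match(d, as.numeric(alb$date))]),
      date = as.Date(d, origin = "1970-01-01")
    )
  })
  dplyr::bind_rows(labs, derived)
}

#' Write a cohort back to the five delimited-text tables
#'
#' Inverse of [load_cohort()]: writes `patients.csv`, `diagnoses.csv`,
#' `prescriptions.csv`, `labs.csv` and `visits.csv` into `dir`. Loading the
#' written tables reproduces the cohort exactly.
#'
#' @param cohort A `pad_cohort` (list of `pad_record`s).
#' @param dir Output directory (created if absent).
#' @return Named character vector of the five file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt_date <- function(d) format(d, "%Y-%m-%d")
  patients <- purrr::map_dfr(cohort, function(r) {
    tibble::tibble(
      patient_id = r$patient_id,
      birth_date = fmt_date(r$birth_date),
      sex = r$sex,
      enrollment_start = fmt_date(r$enrollment_start),
      enrollment_end = if (is.na(r$enrollment_end)) NA_character_
                       else fmt_date(r$enrollment_end)
    )
  })
  stream_tbl <- function(field, cols_fun) {
    purrr::map_dfr(cohort, function(r) {
      s <- r[[field]]
      if (nrow(s) == 0) return(NULL)
      dplyr::bind_cols(tibble::tibble(patient_id = r$patient_id), cols_fun(s))
    })
  }
  diagnoses <- stream_tbl("diagnoses", function(s)
    tibble::tibble(icpc_code = s$icpc_code, date = fmt_date(s$date)))
  prescriptions <- stream_tbl("prescriptions", function(s)
    tibble::tibble(atc_code = s$atc_code, date = fmt_date(s$date)))
  labs <- stream_tbl("labs", function(s)
    tibble::tibble(analyte = s$analyte, value_g_per_l = s$value,
                   date = fmt_date(s$date)))
  visits <- stream_tbl("visits", function(s)
    tibble::tibble(date = fmt_date(s$date), modality = s$modality))

  ensure_cols <- function(df, cols) {
    if (is.null(df) || nrow(df) == 0) {
      df <- tibble::as_tibble(setNames(rep(list(character()), length(cols)), cols))
    }
    df[cols]
  }
  out <- c(patients = file.path(dir, "patients.csv"),
           diagnoses = file.path(dir, "diagnoses.csv"),
           prescriptions = file.path(dir, "prescriptions.csv"),
           labs = file.path(dir, "labs.csv"),
           visits = file.path(dir, "visits.csv"))
  readr::write_csv(ensure_cols(patients, cohort_table_schemas$patients),
                   out[["patients"]], na = "")
  readr::write_csv(ensure_cols(diagnoses, cohort_table_schemas$diagnoses),
                   out[["diagnoses"]], na = "")
  readr::write_csv(ensure_cols(prescriptions, cohort_table_schemas$prescriptions),
                   out[["prescriptions"]], na = "")
  readr::write_csv(ensure_cols(labs, cohort_table_schemas$labs),
                   out[["labs"]], na = "")
  readr::write_csv(ensure_cols(visits, cohort_table_schemas$visits),
                   out[["visits"]], na = "")
  invisible(out)
}

results_columns <- c("patient_id", "censoring_date", "eligible",
                     "exclusion_reason", "antibiotic_score",
                     "respiratory_tract_infections", "gastro_intestinal",
                     "other_infections", "auto_immune",
                     "malignancy_lymphoproliferative_other",
                     "lab_score", "visit_score", "total_score")

#' Write screening results to a delimited-text file
#'
#' One row per patient with the fixed column order: `patient_id`,
#' `censoring_date`, `eligible`, `exclusion_reason`, `antibiotic_score`, the
#' five category subscores (`respiratory_tract_infections`,
#' `gastro_intestinal`, `other_infections`, `auto_immune`,
#' `malignancy_lymphoproliferative_other`), `lab_score`, `visit_score`,
#' `total_score`. Ineligible patients carry their exclusion reason and empty
#' score cells.
#'
#' @param results List of `pad_screening_result`s (see [score_patient()]),
#'   or a `pad_screening_set` from [screen_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  tbl <- results_table(results)
  tbl$censoring_date <- format(tbl$censoring_date, "%Y-%m-%d")
  readr::write_csv(tbl, path, na = "")
  invisible(path)
}

#' Tabulate screening results
#'
#' @inheritParams write_results
#' @return A tibble with the [write_results()] column order.
#' @export
results_table <- function(results) {
  if (inherits(results, "pad_screening_set")) results <- results$results
  if (inherits(results, "pad_screening_result")) results <- list(results)
  if (length(results) == 0) {
    tbl <- tibble::tibble(
      patient_id = character(), censoring_date = as.Date(character()),
      eligible = logical(), exclusion_reason = character(),
      antibiotic_score = numeric(), respiratory_tract_infections = numeric(),
      gastro_intestinal = numeric(), other_infections = numeric(),
      auto_immune = numeric(), malignancy_lymphoproliferative_other = numeric(),
      lab_score = numeric(), visit_score = numeric(), total_score = numeric()
    )
    return(tbl[results_columns])
  }
  purrr::map_dfr(results, function(r) {
    cs <- r$category_scores
    tibble::tibble(
      patient_id = r$patient_id,
      censoring_date = r$censoring_date,
      eligible = r$eligibility$eligible,
      exclusion_reason = if (r$eligibility$eligible) NA_character_
                         else as.character(r$eligibility$reason),
      antibiotic_score = r$antibiotic_score,
      respiratory_tract_infections = cs[["respiratory_tract_infections"]],
      gastro_intestinal = cs[["gastro_intestinal"]],
      other_infections = cs[["other_infections"]],
      auto_immune = cs[["auto_immune"]],
      malignancy_lymphoproliferative_other = cs[["malignancy_lymphoproliferative_other"]],
      lab_score = r$lab_score,
      visit_score = r$visit_score,
      total_score = r$total_score
    )
  })
}
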