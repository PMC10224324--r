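#' @title Scoring engine
#' @description
#' The risk score is the sum of four blocks evaluated against the censored
#' record: (1) weighted antibiotic prescriptions in the 4 years before the
#' censoring date, normalised for short enrollment; (2) weighted presence of
#' diagnosis codes in five categories, each with its own look-back window;
#' (3) weighted low immunoglobulin / calculated-globulin results at any time;
#' (4) three points when the patient visited the GP at least six times in the
#' year before the censoring date. All windows are half-open day windows
#' `(censoring_date - N days, censoring_date]` with a 365-day year.
#' @name scoring
NULL

antibiotic_fired <- function(record, censoring_date, ruleset) {
  rs <- ruleset
  win_days <- rs$antibiotic_window_years * 365
  rx <- record$prescriptions
  min_age_date <- nth_birthday(record$birth_date, rs$antibiotic_min_age_years)
  rx <- rx[in_window(rx$date, censoring_date, win_days) & rx$date >= min_age_date, ,
           drop = FALSE]
  rx <- rx[rx$atc_code %in% rs$antibiotics$atc_code, , drop = FALSE]

  end <- censoring_date
  if (!is.na(record$enrollment_end)) end <- min(end, record$enrollment_end)
  days_enrolled <- as.numeric(end - record$enrollment_start)
  if (days_enrolled <= 0) {
    abort(paste0("Patient ", record$patient_id,
                 ": no observable enrollment before the censoring date"))
  }
  factor <- if (days_enrolled < win_days) {
    if (days_enrolled < 90) {
      warn(paste0("Patient ", record$patient_id, ": only ", days_enrolled,
                  " days enrolled; enrollment-normalised antibiotic score is an ",
                  "unstable extrapolation"))
    }
    rs$antibiotic_window_years / (days_enrolled / 365)
  } else {
    1
  }
  if (nrow(rx) == 0) {
    return(tibble::tibble(component_id = character(), points = numeric()))
  }
  counts <- table(rx$atc_code)
  w <- rs$antibiotics$weight[match(names(counts), rs$antibiotics$atc_code)]
  tibble::tibble(
    component_id = paste0("atc:", names(counts)),
    points = as.numeric(counts) * w * factor
  )
}

#' Antibiotic block score
#'
#' Sum of rule weights over antibiotic prescriptions in the 4-year window
#' before the censoring date (events before the sixth birthday never count;
#' repeat prescriptions accumulate). If the patient is enrolled for fewer
#' than 4 x 365 days before the censoring date, the weighted sum is
#' multiplied by `4 / (days_enrolled / 365)`.
#'
#' @param record A (typically truncated) [patient_record()].
#' @param censoring_date `Date`.
#' @param ruleset A `pad_ruleset`.
#' @return Non-negative number.
#' @export
antibiotic_score <- function(record, censoring_date, ruleset = default_ruleset()) {
  sum(antibiotic_fired(record, censoring_date, ruleset)$points)
}

icpc_fired <- function(record, censoring_date, category, ruleset) {
  if (!category %in% icpc_categories()) {
    abort(paste0("Unknown ICPC category: ", category))
  }
  rules <- ruleset$icpc[ruleset$icpc$category == category, , drop = FALSE]
  win_days <- category_window_days(ruleset, category)
  dx <- record$diagnoses
  dx <- dx[in_window(dx$date, censoring_date, win_days), , drop = FALSE]
  present <- vapply(rules$codes, function(codes) any(dx$icpc_code %in% codes),
                    logical(1))
  tibble::tibble(
    component_id = paste0("icpc:", rules$component_id[present]),
    points = rules$weight[present]
  )
}

#' Diagnosis-category block score
#'
#' Presence semantics: each component contributes its weight at most once,
#' when at least one diagnosis event with one of its codes falls inside the
#' category's window (10 years for respiratory-tract-infection and
#' gastro-intestinal codes, the whole record for the other three categories).
#'
#' @inheritParams antibiotic_score
#' @param category One of [icpc_categories()].
#' @return Non-negative number.
#' @export
icpc_category_score <- function(record, censoring_date, category,
                                ruleset = default_ruleset()) {
  sum(icpc_fired(record, censoring_date, category, ruleset)$points)
}

lab_fired <- function(record, censoring_date, ruleset) {
  labs <- record$labs
  labs <- labs[labs$date <= censoring_date, , drop = FALSE]
  fired <- vapply(seq_len(nrow(ruleset$labs)), function(i) {
    rule <- ruleset$labs[i, ]
    any(labs$analyte == rule$analyte & labs$value < rule$threshold)
  }, logical(1))
  tibble::tibble(
    component_id = paste0("lab:", ruleset$labs$analyte[fired]),
    points = ruleset$labs$weight[fired]
  )
}

#' Laboratory block score
#'
#' Each analyte scores its weight at most once when any result at any time
#' before or on the censoring date lies strictly below its threshold. A
#' value exactly at the threshold does not score. Calculated-globulin
#' results — stored or derived at load time — participate like any analyte.
#'
#' @inheritParams antibiotic_score
#' @return Non-negative number.
#' @export
lab_score <- function(record, censoring_date, ruleset = default_ruleset()) {
  sum(lab_fired(record, censoring_date, ruleset)$points)
}

#' GP-visit block score
#'
#' Counts visits of both modalities in the year (365 days) before the
#' censoring date; at or above the cut-off (default 6) the rule's weight
#' (default 3) is returned, otherwise 0.
#'
#' @inheritParams antibiotic_score
#' @return 0 or the visit-rule weight.
#' @export
visit_score <- function(record, censoring_date, ruleset = default_ruleset()) {
  v <- ruleset$visits
  n <- sum(in_window(record$visits$date, censoring_date, v$window_days))
  if (n >= v$cutoff) v$weight else 0
}

#' Score one patient
#'
#' Full pipeline: determine the censoring date, check eligibility, truncate
#' the record, evaluate the four scoring blocks and sum them. Ineligible
#' patients get a result with the eligibility verdict populated and `NA`
#' scores.
#'
#' @param record A [patient_record()].
#' @param run_date Screening run date.
#' @param ruleset A `pad_ruleset`.
#' @return A `pad_screening_result`: `patient_id`, `censoring_date`,
#'   `censored_by`, `ambiguous_code`, `eligibility`, `antibiotic_score`,
#'   `category_scores` (named vector over the five categories), `lab_score`,
#'   `visit_score`, `total_score`, and `fired_components` (tibble of
#'   component id and contributed points).
#' @export
#' @examples
#' rec <- patient_record("p1", "1980-01-01", "F", "2005-01-01",
#'   diagnoses = data.frame(icpc_code = "R81", date = "2020-05-01"))
#' score_patient(rec, "2021-11-18")$total_score  # 3
score_patient <- function(record, run_date, ruleset = default_ruleset()) {
  censored <- determine_censoring_date(record, run_date, ruleset)
  elig <- check_eligibility(record, censored, ruleset)
  base <- list(
    patient_id = record$patient_id,
    censoring_date = censored$censoring_date,
    censored_by = censored$censored_by,
    ambiguous_code = censored$ambiguous_code,
    eligibility = elig
  )
  cats <- icpc_categories()
  if (!elig$eligible) {
    out <- c(base, list(
      antibiotic_score = NA_real_,
      category_scores = setNames(rep(NA_real_, length(cats)), cats),
      lab_score = NA_real_, visit_score = NA_real_, total_score = NA_real_,
      fired_components = tibble::tibble(component_id = character(),
                                        points = numeric())
    ))
    return(structure(out, class = "pad_screening_result"))
  }
  trunc <- truncate_record(record, censored)
  cd <- censored$censoring_date
  ab <- antibiotic_fired(trunc, cd, ruleset)
  ic <- lapply(setNames(cats, cats),
               function(cat) icpc_fired(trunc, cd, cat, ruleset))
  lb <- lab_fired(trunc, cd, ruleset)
  vs <- visit_score(trunc, cd, ruleset)
  fired <- dplyr::bind_rows(c(list(ab), ic, list(lb)))
  if (vs > 0) {
    fired <- dplyr::bind_rows(fired,
      tibble::tibble(component_id = "visits", points = vs))
  }
  category_scores <- vapply(ic, function(x) sum(x$points), numeric(1))
  out <- c(base, list(
    antibiotic_score = sum(ab$points),
    category_scores = category_scores,
    lab_score = sum(lb$points),
    visit_score = vs,
    total_score = sum(ab$points) + sum(category_scores) + sum(lb$points) + vs,
    fired_components = fired
  ))
  structure(out, class = "pad_screening_result")
}

#' @export
print.pad_screening_result <- function(x, ...) {
  cat("<pad_screening_result>", x$patient_id, "\n")
  cat("  censoring date:", format(x$censoring_date), "(", x$censored_by, ")\n")
  if (!x$eligibility$eligible) {
    cat("  INELIGIBLE:", x$eligibility$reason,
        if (!is.na(x$eligibility$triggering_code)) x$eligibility$triggering_code else "",
        "\n")
    return(invisible(x))
  }
  cat("  antibiotic:", x$antibiotic_score, "| labs:", x$lab_score,
      "| visits:", x$visit_score, "\n")
  for (cat_name in names(x$category_scores)) {
    if (x$category_scores[[cat_name]] > 0) {
      cat("  ", cat_name, ":", x$category_scores[[cat_name]], "\n")
    }
  }
  cat("  TOTAL:", x$total_score, "\n")
  invisible(x)
}

#' Screen a cohort and rank patients
#'
#' Scores every record, ranks eligible patients by total score (descending;
#' ties broken by `patient_id` ascending for determinism) and flags either
#' the top `k` patients or all patients at or above a score threshold.
#' Ineligible patients are listed after the ranked ones, unranked.
#'
#' @param cohort A `pad_cohort` or list of [patient_record()]s.
#' @param run_date Screening run date.
#' @param ruleset A `pad_ruleset`.
#' @param top_k Flag the `k` highest-scoring eligible patients.
#' @param threshold Flag eligible patients with `total_score >= threshold`.
#'   Exactly one of `top_k` / `threshold` must be given.
#' @return A `pad_screening_set`: `results` (ordered list of
#'   `pad_screening_result`s), `table` (ranked tibble with a `flagged`
#'   column), `flagged` (character vector of flagged patient ids).
#' @export
screen_cohort <- function(cohort, run_date, ruleset = default_ruleset(),
                          top_k = NULL, threshold = NULL) {
  if (is.null(top_k) == is.null(threshold)) {
    abort("Specify exactly one of top_k or threshold")
  }
  if (!is.null(top_k) && top_k < 1) abort("top_k must be >= 1")
  if (!is.null(threshold) && threshold < 0) abort("threshold must be >= 0")
  results <- lapply(cohort, function(r) score_patient(r, run_date, ruleset))
  eligible <- vapply(results, function(r) r$eligibility$eligible, logical(1))
  ids <- vapply(results, function(r) r$patient_id, character(1))
  scores <- vapply(results, function(r) {
    if (r$eligibility$eligible) r$total_score else -Inf
  }, numeric(1))
  ord_el <- order(-scores[eligible], ids[eligible])
  ordered <- c(results[eligible][ord_el], results[!eligible][order(ids[!eligible])])
  tbl <- results_table(ordered)
  n_el <- sum(eligible)
  tbl$rank <- c(seq_len(n_el), rep(NA_integer_, sum(!eligible)))
  flagged <- rep(FALSE, nrow(tbl))
  if (!is.null(top_k)) {
    flagged[seq_len(min(top_k, n_el))] <- TRUE
  } else {
    flagged[seq_len(n_el)] <- tbl$total_score[seq_len(n_el)] >= threshold
  }
  tbl$flagged <- flagged
  structure(list(
    results = ordered,
    table = tbl,
    flagged = tbl$patient_id[tbl$flagged]
  ), class = "pad_screening_set")
}

#' @export
print.pad_screening_set <- function(x, ...) {
  cat("<pad_screening_set>:", length(x$results), "patients,",
      length(x$flagged), "flagged\n")
  print(head(x$table, 10))
  invisible(x)
}

#' Per-patient explanation report
#'
#' One line per fired component (block, component id, points), suitable for
#' review by the treating GP.
#'
#' @param result A `pad_screening_result`.
#' @return A tibble with columns `patient_id`, `component_id`, `points`.
#' @export
explain_result <- function(result) {
  fc <- result$fired_components
  if (nrow(fc) == 0) {
    return(tibble::tibble(patient_id = character(), component_id = character(),
                          points = numeric()))
  }
  tibble::tibble(patient_id = result$patient_id,
                 component_id = fc$component_id, points = fc$points)
}
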