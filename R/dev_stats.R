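#' Censor and truncate a whole cohort
#'
#' Applies [determine_censoring_date()] and [truncate_record()] to each
#' record. For case groups the censoring anchor can be each patient's
#' diagnosis date (carried by the synthetic generator as a `diagnosis_date`
#' attribute, or supplied explicitly), so that pre-diagnosis statistics can
#' be computed; an earlier ambiguous diagnosis still takes precedence.
#'
#' @param cohort A `pad_cohort` or list of [patient_record()]s.
#' @param run_date Scalar date, or a vector of per-patient anchor dates
#'   (e.g. diagnosis dates) recycled against the cohort.
#' @param ruleset A `pad_ruleset`.
#' @param use_diagnosis_date If `TRUE`, records carrying a `diagnosis_date`
#'   attribute are censored at that date instead of `run_date`.
#' @return List of lists with fields `record` (truncated), `censoring_date`,
#'   `censored_by`, `ambiguous_code`.
#' @export
censor_cohort <- function(cohort, run_date, ruleset = default_ruleset(),
                          use_diagnosis_date = FALSE) {
  run_date <- as_date_strict(run_date, "run_date")
  anchors <- rep(run_date, length.out = length(cohort))
  purrr::map2(unname(cohort), seq_along(cohort), function(rec, i) {
    anchor <- anchors[i]
    if (use_diagnosis_date) {
      dd <- attr(rec, "diagnosis_date", exact = TRUE)
      if (!is.null(dd) && !is.na(dd)) anchor <- as.Date(dd)
    }
    cen <- determine_censoring_date(rec, anchor, ruleset)
    list(record = truncate_record(rec, cen),
         censoring_date = cen$censoring_date,
         censored_by = cen$censored_by,
         ambiguous_code = cen$ambiguous_code)
  })
}

#' Does a component fire for a censored record?
#'
#' @param record A censored, truncated [patient_record()].
#' @param censoring_date The record's censoring date.
#' @param component A component id as returned by [component_ids()]
#'   (`"atc:<code>"`, `"icpc:<codes>"`, `"lab:<analyte>"`, `"visits"`).
#' @param ruleset A `pad_ruleset`.
#' @return `TRUE` iff the component would contribute points under its window
#'   semantics (for antibiotic components: at least one in-window
#'   prescription).
#' @export
component_presence <- function(record, censoring_date, component,
                               ruleset = default_ruleset()) {
  if (!component %in% component_ids(ruleset)) {
    abort(paste0("Unknown component: ", component))
  }
  if (component == "visits") {
    return(visit_score(record, censoring_date, ruleset) > 0)
  }
  fired <- if (startsWith(component, "atc:")) {
    antibiotic_fired(record, censoring_date, ruleset)
  } else if (startsWith(component, "lab:")) {
    lab_fired(record, censoring_date, ruleset)
  } else {
    cat_name <- ruleset$icpc$category[
      paste0("icpc:", ruleset$icpc$component_id) == component]
    icpc_fired(record, censoring_date, cat_name, ruleset)
  }
  component %in% fired$component_id
}

presence_fraction <- function(censored_cohort, component, ruleset) {
  hits <- vapply(censored_cohort, function(x) {
    component_presence(x$record, x$censoring_date, component, ruleset)
  }, logical(1))
  mean(hits)
}

#' Youden's index for one component
#'
#' Sensitivity is computed separately in the confirmed-PAD and primary-care
#' immunodeficiency case groups and averaged; specificity is computed in the
#' general-population control group; Youden's index is
#' `mean sensitivity + specificity - 1`.
#'
#' @param pad_cases,pcid_cases,controls Censored cohorts from
#'   [censor_cohort()]; all non-empty.
#' @param component A component id ([component_ids()]).
#' @param ruleset A `pad_ruleset`.
#' @return One-row tibble: `component`, `sensitivity_pad`, `sensitivity_pcid`,
#'   `mean_sensitivity`, `specificity`, `youden`.
#' @export
youden_index <- function(pad_cases, pcid_cases, controls, component,
                         ruleset = default_ruleset()) {
  for (nm in c("pad_cases", "pcid_cases", "controls")) {
    if (length(get(nm)) == 0) abort(paste0("Empty cohort: ", nm))
  }
  sens_pad <- presence_fraction(pad_cases, component, ruleset)
  sens_pcid <- presence_fraction(pcid_cases, component, ruleset)
  spec <- 1 - presence_fraction(controls, component, ruleset)
  mean_sens <- (sens_pad + sens_pcid) / 2
  tibble::tibble(
    component = component,
    sensitivity_pad = sens_pad,
    sensitivity_pcid = sens_pcid,
    mean_sensitivity = mean_sens,
    specificity = spec,
    youden = mean_sens + spec - 1
  )
}

#' Component diagnostics for every component in the rule set
#'
#' @inheritParams youden_index
#' @return Tibble with one [youden_index()] row per component.
#' @export
component_diagnostics <- function(pad_cases, pcid_cases, controls,
                                  ruleset = default_ruleset()) {
  purrr::map_dfr(component_ids(ruleset), function(comp) {
    youden_index(pad_cases, pcid_cases, controls, comp, ruleset)
  })
}

feature_count <- function(x, feature, window_days) {
  rec <- x$record
  cd <- x$censoring_date
  dates <- switch(feature,
    visits = rec$visits$date,
    lung_function_requests = ,
    infection_blood_requests = rec$labs$date,
    abort(paste0("Unknown count feature: ", feature))
  )
  sum(in_window(dates, cd, window_days))
}

#' Sweep candidate cut-offs for a count criterion
#'
#' Evaluates the binary component "count of `count_feature` events in the
#' 1-year pre-censoring window >= c" at each candidate cut-off and selects
#' the one maximising Youden's index (ties broken toward the smallest
#' cut-off). This is the procedure that fixed the >= 6 visits criterion.
#' When no candidates are given, the integer range `median(PAD counts) - 3`
#' to `median + 3` (clipped below at 1) is used. The structured record keeps
#' no dedicated test-request stream, so the two request features count
#' laboratory result events as their observable proxy.
#'
#' @inheritParams youden_index
#' @param count_feature `"visits"`, `"lung_function_requests"` or
#'   `"infection_blood_requests"`.
#' @param candidate_cutoffs Positive integer vector, or `NULL` for the
#'   median-centred default.
#' @param window_days Window length (default 365).
#' @return A list: `table` (tibble of cutoff, sensitivities, specificity,
#'   youden) and `selected` (the chosen cut-off).
#' @export
cutoff_sweep <- function(pad_cases, pcid_cases, controls,
                         count_feature = c("visits", "lung_function_requests",
                                           "infection_blood_requests"),
                         candidate_cutoffs = NULL,
                         ruleset = default_ruleset(), window_days = 365) {
  count_feature <- match.arg(count_feature)
  for (nm in c("pad_cases", "pcid_cases", "controls")) {
    if (length(get(nm)) == 0) abort(paste0("Empty cohort: ", nm))
  }
  counts <- lapply(list(pad = pad_cases, pcid = pcid_cases, ctrl = controls),
                   function(coh) vapply(coh, feature_count, numeric(1),
                                        feature = count_feature,
                                        window_days = window_days))
  if (is.null(candidate_cutoffs)) {
    med <- median(counts$pad)
    candidate_cutoffs <- seq(max(1, floor(med) - 3), floor(med) + 3)
  }
  if (length(candidate_cutoffs) == 0 || any(candidate_cutoffs < 1)) {
    abort("candidate_cutoffs must be positive integers")
  }
  tbl <- purrr::map_dfr(sort(unique(as.integer(candidate_cutoffs))), function(cut) {
    sens_pad <- mean(counts$pad >= cut)
    sens_pcid <- mean(counts$pcid >= cut)
    spec <- mean(counts$ctrl < cut)
    tibble::tibble(
      cutoff = cut,
      sensitivity_pad = sens_pad,
      sensitivity_pcid = sens_pcid,
      mean_sensitivity = (sens_pad + sens_pcid) / 2,
      specificity = spec,
      youden = (sens_pad + sens_pcid) / 2 + spec - 1
    )
  })
  list(table = tbl, selected = tbl$cutoff[which.max(tbl$youden)])
}

#' Descriptive summary of a censored cohort
#'
#' Computes the descriptive statistics used to compare patient groups:
#' mean antibiotic prescription counts per pre-censoring year (years -10 to
#' -1, bins `(censor - k*365, censor - (k-1)*365]`), the mean total
#' prescription count over the 4-year window, the median GP-visit count
#' (both modalities) in the 1-year window, and per-analyte laboratory means,
#' SDs and patient counts over the 10-year window, computed only over
#' patients with at least one result for the analyte.
#'
#' @param censored_cohort A censored cohort from [censor_cohort()].
#' @param ruleset A `pad_ruleset`.
#' @param label Group label stored in the summary.
#' @return A `pad_group_summary`: `label`, `n`, `rx_per_year` (named numeric,
#'   `year_-10` .. `year_-1`), `rx_4yr_mean`, `visit_median_1yr`, `labs`
#'   (tibble `analyte`, `mean`, `sd`, `n`; analytes never requested appear
#'   with `n = 0` and `NA` mean/SD).
#' @export
group_summary <- function(censored_cohort, ruleset = default_ruleset(),
                          label = "group") {
  if (length(censored_cohort) == 0) abort("Empty cohort")
  n <- length(censored_cohort)

  per_year <- vapply(censored_cohort, function(x) {
    rx <- x$record$prescriptions
    vapply(1:10, function(k) {
      sum(rx$date > (x$censoring_date - k * 365) &
            rx$date <= (x$censoring_date - (k - 1) * 365))
    }, numeric(1))
  }, numeric(10))
  per_year_mean <- rowMeans(per_year)          # index k = year -k
  names(per_year_mean) <- paste0("year_-", 1:10)
  per_year_mean <- rev(per_year_mean)          # year_-10 .. year_-1

  rx4 <- vapply(censored_cohort, function(x) {
    sum(in_window(x$record$prescriptions$date, x$censoring_date, 4 * 365))
  }, numeric(1))
  visits1 <- vapply(censored_cohort, function(x) {
    sum(in_window(x$record$visits$date, x$censoring_date, 365))
  }, numeric(1))

  analytes <- setdiff(lab_analytes(), c("total_protein", "albumin"))
  labs <- purrr::map_dfr(analytes, function(an) {
    per_patient <- vapply(censored_cohort, function(x) {
      lb <- x$record$labs
      v <- lb$value[lb$analyte == an &
                      in_window(lb$date, x$censoring_date, 10 * 365)]
      if (length(v) == 0) NA_real_ else mean(v)
    }, numeric(1))
    v <- per_patient[!is.na(per_patient)]
    tibble::tibble(
      analyte = an,
      mean = if (length(v) > 0) mean(v) else NA_real_,
      sd = if (length(v) > 1) sd(v) else if (length(v) == 1) 0 else NA_real_,
      n = length(v)
    )
  })

  structure(list(
    label = label,
    n = n,
    rx_per_year = per_year_mean,
    rx_4yr_mean = mean(rx4),
    rx_4yr_sd = sd(rx4),
    visit_median_1yr = median(visits1),
    visit_counts_1yr = visits1,
    labs = labs
  ), class = "pad_group_summary")
}

#' @export
print.pad_group_summary <- function(x, ...) {
  cat("<pad_group_summary>", x$label, "(n =", x$n, ")\n")
  cat("  mean 4-year antibiotic prescriptions:", round(x$rx_4yr_mean, 2), "\n")
  cat("  median 1-year GP visits:", x$visit_median_1yr, "\n")
  requested <- x$labs[x$labs$n > 0, ]
  if (nrow(requested) > 0) {
    cat("  lab results present for:",
        paste0(requested$analyte, " (n=", requested$n, ")", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Concordance between two binary symptom flags
#'
#' Percentage of patients for whom presence/non-presence agrees between two
#' registration sources (e.g. coded diagnoses in the primary-care record vs
#' free text in the hospital record).
#'
#' @param flags_a,flags_b Logical vectors of equal length (>= 1).
#' @return List with `percent` (rounded to the nearest integer, the reported
#'   form) and `raw` (unrounded percentage).
#' @export
#' @examples
#' concordance(rep(TRUE, 30), c(rep(TRUE, 28), rep(FALSE, 2)))$percent  # 93
concordance <- function(flags_a, flags_b) {
  if (length(flags_a) != length(flags_b)) {
    abort("flags_a and flags_b must have equal length")
  }
  if (length(flags_a) < 1) abort("flags must be non-empty")
  raw <- 100 * mean(flags_a == flags_b)
  list(percent = round(raw), raw = raw)
}
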