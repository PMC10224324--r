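#' Define a synthetic cohort profile
#'
#' A profile parameterises one synthetic patient group: demographic ranges,
#' yearly antibiotic-prescription and GP-visit rates (Poisson within each
#' pre-censoring year), per-code diagnosis prevalences, laboratory request
#' probabilities and value distributions, enrollment-length distribution, and
#' optional injection of exclusion/ambiguous codes. Case profiles carry a
#' diagnosis-date offset so pre-diagnosis censoring can be exercised.
#'
#' @param label Group label, one of `"general"`, `"upper_rti"`,
#'   `"copd_asthma"`, `"ibd"`, `"malignancy"`, `"pc_immunodef"`, `"pad"`
#'   (other labels are allowed for custom groups).
#' @param n Number of patients.
#' @param age_range Length-2 numeric, age in years at the censoring date.
#' @param female_fraction Probability of sex `"F"`.
#' @param antibiotic_rate_per_year Scalar yearly Poisson rate, or a length-10
#'   vector of rates for pre-censoring years -10 .. -1 (a rising ramp).
#' @param visit_rate_per_year Scalar yearly Poisson visit rate.
#' @param icpc_prevalences Named numeric vector, probability that each ICPC
#'   code appears at least once (dated uniformly in the 10 pre-censoring
#'   years).
#' @param lab_request_probability Named numeric vector, per-analyte
#'   probability of having one result.
#' @param lab_value_distribution Named list of `c(mean, sd)` per analyte
#'   (g/L, Gaussian truncated at 0).
#' @param enrollment_years `c(mean, sd)` of the Gaussian enrollment length in
#'   years before the censoring date (clipped below at 1).
#' @param exclusion_code_probability,ambiguous_code_probability Probability
#'   of injecting one random exclusion/ambiguous code.
#' @param diagnosis_date_offset_years `NULL`, or `c(min, max)` years before
#'   the run date at which the synthetic diagnosis (and hence the censoring
#'   anchor) is placed.
#' @return A `pad_profile`.
#' @export
cohort_profile <- function(label, n, age_range = c(12, 70),
                           female_fraction = 0.5,
                           antibiotic_rate_per_year = 0,
                           visit_rate_per_year = 0,
                           icpc_prevalences = numeric(),
                           lab_request_probability = numeric(),
                           lab_value_distribution = list(),
                           enrollment_years = c(15, 5),
                           exclusion_code_probability = 0,
                           ambiguous_code_probability = 0,
                           diagnosis_date_offset_years = NULL) {
  stopifnot(n >= 0, length(age_range) == 2, age_range[1] <= age_range[2])
  probs <- c(female_fraction, icpc_prevalences, lab_request_probability,
             exclusion_code_probability, ambiguous_code_probability)
  if (any(probs < 0 | probs > 1)) abort("All probabilities must be in [0, 1]")
  if (any(antibiotic_rate_per_year < 0) || any(visit_rate_per_year < 0)) {
    abort("Rates must be non-negative")
  }
  if (!length(antibiotic_rate_per_year) %in% c(1, 10)) {
    abort("antibiotic_rate_per_year must have length 1 or 10")
  }
  structure(list(
    label = label, n = as.integer(n), age_range = age_range,
    female_fraction = female_fraction,
    antibiotic_rate_per_year = antibiotic_rate_per_year,
    visit_rate_per_year = visit_rate_per_year,
    icpc_prevalences = icpc_prevalences,
    lab_request_probability = lab_request_probability,
    lab_value_distribution = lab_value_distribution,
    enrollment_years = enrollment_years,
    exclusion_code_probability = exclusion_code_probability,
    ambiguous_code_probability = ambiguous_code_probability,
    diagnosis_date_offset_years = diagnosis_date_offset_years
  ), class = "pad_profile")
}

# Linear ramp over pre-censoring years -10..-1 whose last-4-year mass equals
# `total_4yr`: rate in year -k proportional to (11 - k).
ramp_rates <- function(total_4yr) {
  w <- 11 - (10:1)            # year -10 .. year -1
  w * total_4yr / sum(w[7:10])
}

# Laboratory value distributions (g/L) used for control-group profiles.
control_lab_values <- list(
  IgA_total = c(2.01, 1.06),
  IgG_total = c(10.6, 2.87),
  IgM_total = c(2.63, 4.73),
  IgG1 = c(3.8, 0.5),
  IgG2 = c(3.34, 0.5),
  IgG3 = c(0.67, 0.1),
  IgG4 = c(0.06, 0.02),
  calculated_globulin = c(26.34, 12.12)
)

#' Default synthetic profiles for the seven study groups
#'
#' Ships profiles for the general GP population, four confounder groups
#' (upper respiratory tract infections, COPD/asthma, inflammatory bowel
#' disease, malignancy), primary-care immunodeficiency patients, and
#' confirmed PAD patients. Calibration anchors: the PAD-like profile accrues
#' a mean of 5.14 antibiotic prescriptions over the 4 pre-censoring years
#' (rising linearly over years -10..-1) and GP visits at a Poisson rate whose
#' one-year median is 6; the general-population profile accrues a 4-year mean
#' of 0.48 prescriptions and a visit median of 2. Confounder groups sit in
#' between. Immunoglobulin results are generated only for control groups, at
#' request probabilities of the order seen in routine primary care (about
#' 0.9% of general-population patients with an IgA result); the PAD-like and
#' immunodeficiency profiles generate none pre-diagnosis.
#'
#' @param n Optional named integer vector overriding group sizes (names are
#'   profile labels).
#' @return Named list of seven [cohort_profile()]s.
#' @export
default_profiles <- function(n = NULL) {
  sizes <- c(general = 500L, upper_rti = 200L, copd_asthma = 150L,
             ibd = 100L, malignancy = 100L, pc_immunodef = 26L, pad = 30L)
  if (!is.null(n)) sizes[names(n)] <- as.integer(n)

  general_labs <- c(IgA_total = 0.0093, IgG_total = 0.0011,
                    IgM_total = 0.0012, IgG1 = 2e-05, IgG2 = 2e-05,
                    IgG3 = 2e-05, IgG4 = 2e-05, calculated_globulin = 0.0038)

  profiles <- list(
    general = cohort_profile(
      "general", sizes[["general"]],
      age_range = c(12, 70), female_fraction = 0.529,
      antibiotic_rate_per_year = 0.48 / 4,
      visit_rate_per_year = 2,
      icpc_prevalences = c(R74 = 0.15, R05 = 0.10, D11 = 0.05, A04 = 0.08,
                           T86 = 0.03),
      lab_request_probability = general_labs,
      lab_value_distribution = control_lab_values,
      exclusion_code_probability = 0.002,
      ambiguous_code_probability = 0.001
    ),
    upper_rti = cohort_profile(
      "upper_rti", sizes[["upper_rti"]],
      age_range = c(12, 70), female_fraction = 0.574,
      antibiotic_rate_per_year = 1.5 / 4,
      visit_rate_per_year = 3,
      icpc_prevalences = c(R74 = 1, R75 = 0.15, R05 = 0.2, A04 = 0.08),
      lab_request_probability = c(IgA_total = 0.018, IgG_total = 0.0026,
                                  IgM_total = 0.0026,
                                  calculated_globulin = 0.0068),
      lab_value_distribution = control_lab_values,
      exclusion_code_probability = 0.002,
      ambiguous_code_probability = 0.001
    ),
    copd_asthma = cohort_profile(
      "copd_asthma", sizes[["copd_asthma"]],
      age_range = c(12, 70), female_fraction = 0.532,
      antibiotic_rate_per_year = 2 / 4,
      visit_rate_per_year = 4,
      icpc_prevalences = c(R96 = 1, R05 = 0.3, R78 = 0.2),
      lab_request_probability = c(IgA_total = 0.014, IgG_total = 0.0025,
                                  IgM_total = 0.0025,
                                  calculated_globulin = 0.0086),
      lab_value_distribution = control_lab_values,
      exclusion_code_probability = 0.002,
      ambiguous_code_probability = 0.001
    ),
    ibd = cohort_profile(
      "ibd", sizes[["ibd"]],
      age_range = c(18, 70), female_fraction = 0.546,
      antibiotic_rate_per_year = 1 / 4,
      visit_rate_per_year = 3,
      icpc_prevalences = c(D94 = 0.5, D94.02 = 0.5, D11 = 0.3),
      lab_request_probability = c(IgA_total = 0.025,
                                  calculated_globulin = 0.0074),
      lab_value_distribution = control_lab_values,
      exclusion_code_probability = 0.002,
      ambiguous_code_probability = 0.001
    ),
    malignancy = cohort_profile(
      "malignancy", sizes[["malignancy"]],
      age_range = c(30, 70), female_fraction = 0.605,
      antibiotic_rate_per_year = 1 / 4,
      visit_rate_per_year = 4,
      icpc_prevalences = c(X76 = 0.4, Y77 = 0.3, T08 = 0.15, A04 = 0.2),
      lab_request_probability = c(IgA_total = 0.016, IgG_total = 0.0059,
                                  IgM_total = 0.0066,
                                  calculated_globulin = 0.015),
      lab_value_distribution = control_lab_values,
      exclusion_code_probability = 0.02,
      ambiguous_code_probability = 0.05
    ),
    pc_immunodef = cohort_profile(
      "pc_immunodef", sizes[["pc_immunodef"]],
      age_range = c(12, 60), female_fraction = 0.538,
      antibiotic_rate_per_year = ramp_rates(4.5),
      visit_rate_per_year = 6,
      icpc_prevalences = c(R74 = 0.8, R75 = 0.4, R81 = 0.3, D11 = 0.4,
                           B82 = 0.15, R91.02 = 0.15, N71 = 0.1, A04 = 0.3),
      diagnosis_date_offset_years = c(0.5, 5)
    ),
    pad = cohort_profile(
      "pad", sizes[["pad"]],
      age_range = c(12, 45), female_fraction = 0.40,
      antibiotic_rate_per_year = ramp_rates(5.14),
      visit_rate_per_year = 6,
      icpc_prevalences = c(R74 = 1, R75 = 0.5, R81 = 0.37, D11 = 0.57,
                           B82 = 0.2, R91.02 = 0.2, N71 = 0.13, A04 = 0.3),
      diagnosis_date_offset_years = c(0.5, 5)
    )
  )
  profiles
}

#' Generate a synthetic cohort from a profile
#'
#' Draws `profile$n` patients. Event counts follow homogeneous Poisson
#' processes within each pre-censoring year (antibiotic rates may ramp over
#' years -10..-1); visit events are generated over the last two pre-censoring
#' years (the scoring and summary windows only inspect the final year);
#' diagnosis codes are injected per prevalence with dates uniform over the 10
#' pre-censoring years; laboratory results are drawn per request probability
#' with truncated-Gaussian values. Case profiles place a synthetic diagnosis
#' date between `diagnosis_date_offset_years` before the run date and censor
#' all event generation there; the date is attached to each record as the
#' `diagnosis_date` attribute.
#'
#' @param profile A [cohort_profile()].
#' @param run_date Run (extraction) date.
#' @param seed Integer seed; output is a pure function of
#'   `(profile, run_date, seed)`.
#' @param ruleset Rule set supplying the ATC/exclusion/ambiguous code pools.
#' @return A `pad_cohort` (named list of [patient_record()]s), each record
#'   carrying `group` and `diagnosis_date` attributes.
#' @export
generate_cohort <- function(profile, run_date, seed,
                            ruleset = default_ruleset()) {
  if (!inherits(profile, "pad_profile")) abort("profile must be a pad_profile")
  if (missing(seed) || is.null(seed)) abort("seed is mandatory")
  run_date <- as_date_strict(run_date, "run_date")
  set.seed(as.integer(seed) %% .Machine$integer.max)

  n <- profile$n
  if (n == 0) return(structure(setNames(list(), character()), class = "pad_cohort"))
  rates <- profile$antibiotic_rate_per_year
  if (length(rates) == 1) rates <- rep(rates, 10)   # year -10 .. -1 order
  atc_pool <- ruleset$antibiotics$atc_code

  records <- vector("list", n)
  ids <- sprintf("%s_%04d", profile$label, seq_len(n))
  for (i in seq_len(n)) {
    anchor <- run_date
    diagnosis_date <- as.Date(NA)
    if (!is.null(profile$diagnosis_date_offset_years)) {
      off <- runif(1, profile$diagnosis_date_offset_years[1],
                   profile$diagnosis_date_offset_years[2])
      diagnosis_date <- run_date - round(off * 365.25)
      anchor <- diagnosis_date
    }
    age <- runif(1, profile$age_range[1], profile$age_range[2])
    birth <- anchor - round(age * 365.25)
    enroll_years <- max(1, rnorm(1, profile$enrollment_years[1],
                                 profile$enrollment_years[2]))
    enroll_start <- max(birth, anchor - round(enroll_years * 365.25))
    enroll_end <- run_date

    year_dates <- function(k, count) {
      # uniform dates in (anchor - k*365, anchor - (k-1)*365]
      anchor - (k - 1) * 365 - floor(runif(count) * 365)
    }
    # rates is ordered year -10 .. -1; element j corresponds to year -(11 - j)
    rx_counts <- rpois(10, rates)
    rx_dates <- as.Date(character())
    for (j in 1:10) {
      k <- 11 - j                               # look-back year index
      if (rx_counts[j] > 0) rx_dates <- c(rx_dates, year_dates(k, rx_counts[j]))
    }
    prescriptions <- tibble::tibble(
      atc_code = if (length(rx_dates) > 0)
        sample(atc_pool, length(rx_dates), replace = TRUE) else character(),
      date = as.Date(rx_dates, origin = "1970-01-01")
    )

    visit_counts <- rpois(2, profile$visit_rate_per_year)  # years -2, -1
    visit_dates <- c(
      if (visit_counts[1] > 0) year_dates(2, visit_counts[1]),
      if (visit_counts[2] > 0) year_dates(1, visit_counts[2])
    )
    visits <- tibble::tibble(
      date = as.Date(if (is.null(visit_dates)) numeric() else visit_dates,
                     origin = "1970-01-01"),
      modality = if (length(visit_dates) > 0)
        sample(c("physical", "electronic"), length(visit_dates),
               replace = TRUE, prob = c(0.7, 0.3)) else character()
    )

    dx_codes <- character()
    dx_dates <- as.Date(character())
    prev <- profile$icpc_prevalences
    if (length(prev) > 0) {
      hit <- runif(length(prev)) < prev
      if (any(hit)) {
        dx_codes <- names(prev)[hit]
        dx_dates <- anchor - floor(runif(sum(hit)) * (10 * 365))
      }
    }
    # injected exclusion/ambiguous codes are placed inside the enrollment
    # interval (an ambiguous censoring date must leave observable enrollment)
    enrolled_days_back <- min(10 * 365, as.numeric(anchor - enroll_start) - 1)
    if (profile$exclusion_code_probability > 0 &&
        runif(1) < profile$exclusion_code_probability) {
      dx_codes <- c(dx_codes, sample(ruleset$exclusions$icpc_code, 1))
      dx_dates <- c(dx_dates, anchor - floor(runif(1) * enrolled_days_back))
    }
    if (profile$ambiguous_code_probability > 0 &&
        runif(1) < profile$ambiguous_code_probability) {
      dx_codes <- c(dx_codes, sample(ruleset$ambiguous$icpc_code, 1))
      dx_dates <- c(dx_dates, anchor - floor(runif(1) * enrolled_days_back))
    }
    dx_dates <- pmax(as.Date(dx_dates, origin = "1970-01-01"), birth)
    diagnoses <- tibble::tibble(icpc_code = dx_codes, date = dx_dates)

    lab_rows <- list()
    lrp <- profile$lab_request_probability
    for (an in names(lrp)) {
      if (runif(1) < lrp[[an]]) {
        dist <- profile$lab_value_distribution[[an]]
        if (is.null(dist)) dist <- c(1, 0.2)
        lab_rows[[length(lab_rows) + 1]] <- tibble::tibble(
          analyte = an,
          value = max(0, rnorm(1, dist[1], dist[2])),
          date = anchor - floor(runif(1) * (10 * 365))
        )
      }
    }
    labs <- if (length(lab_rows) > 0) dplyr::bind_rows(lab_rows) else NULL

    rec <- patient_record(
      patient_id = ids[i],
      birth_date = birth,
      sex = if (runif(1) < profile$female_fraction) "F" else "M",
      enrollment_start = enroll_start,
      enrollment_end = enroll_end,
      diagnoses = diagnoses,
      prescriptions = prescriptions,
      labs = labs,
      visits = visits
    )
    attr(rec, "group") <- profile$label
    attr(rec, "diagnosis_date") <- diagnosis_date
    records[[i]] <- rec
  }
  structure(setNames(records, ids), class = "pad_cohort")
}

#' Generate and write a full multi-group study
#'
#' Generates one cohort per profile and writes each as the five delimited
#' tables under `out_dir/<label>/`, plus a `manifest.yaml` recording the
#' seed, run date and every profile parameter — sufficient to regenerate the
#' study byte-identically. Each group's cohort uses seed
#' `seed + <group index>`. For case groups a sixth table
#' `diagnosis_dates.csv` records each patient's synthetic diagnosis date.
#'
#' @param config List with fields `profiles` (list of [cohort_profile()]s),
#'   `run_date`, `seed`.
#' @param out_dir Output directory.
#' @param ruleset A `pad_ruleset`.
#' @return Invisibly, a named list of the generated cohorts.
#' @export
generate_mixed_study <- function(config, out_dir, ruleset = default_ruleset()) {
  if (is.null(config$seed)) abort("config$seed is mandatory")
  if (is.null(config$run_date)) abort("config$run_date is mandatory")
  profiles <- config$profiles
  labels <- vapply(profiles, function(p) p$label, character(1))
  if (anyDuplicated(labels)) abort("Profile labels must be unique")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  cohorts <- list()
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    coh <- generate_cohort(p, config$run_date, seed = config$seed + i, ruleset)
    gdir <- file.path(out_dir, p$label)
    write_cohort(coh, gdir)
    dd <- vapply(coh, function(r) {
      d <- attr(r, "diagnosis_date", exact = TRUE)
      if (is.null(d) || is.na(d)) NA_character_ else format(d, "%Y-%m-%d")
    }, character(1))
    if (any(!is.na(dd))) {
      readr::write_csv(tibble::tibble(patient_id = names(coh),
                                      diagnosis_date = dd),
                       file.path(gdir, "diagnosis_dates.csv"), na = "")
    }
    cohorts[[p$label]] <- coh
  }
  manifest <- list(
    seed = config$seed,
    run_date = format(as_date_strict(config$run_date, "run_date"), "%Y-%m-%d"),
    package_version = as.character(utils::packageVersion("padscreen")),
    groups = lapply(profiles, function(p) {
      out <- unclass(p)
      out$age_range <- as.numeric(out$age_range)
      out$icpc_prevalences <- as.list(out$icpc_prevalences)
      out$lab_request_probability <- as.list(out$lab_request_probability)
      out$lab_value_distribution <- lapply(out$lab_value_distribution, as.numeric)
      out
    })
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(cohorts)
}

#' Read a simulation manifest/config back into a config list
#'
#' Accepts either a hand-written simulation config (`seed`, `run_date`,
#' `profiles: default` or a full group list) or a manifest written by
#' [generate_mixed_study()], enabling exact regeneration.
#'
#' @param path YAML file path.
#' @return A config list usable with [generate_mixed_study()].
#' @export
read_simulation_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) abort("Simulation config must include a seed")
  if (is.null(cfg$run_date)) abort("Simulation config must include a run_date")
  groups <- if (!is.null(cfg$groups)) cfg$groups else cfg$profiles
  profiles <- if (identical(groups, "default")) {
    default_profiles()
  } else {
    lapply(groups, function(g) {
      cohort_profile(
        label = g$label, n = g$n,
        age_range = as.numeric(unlist(g$age_range)),
        female_fraction = g$female_fraction,
        antibiotic_rate_per_year = as.numeric(unlist(g$antibiotic_rate_per_year)),
        visit_rate_per_year = g$visit_rate_per_year,
        icpc_prevalences = unlist(g$icpc_prevalences) %||% numeric(),
        lab_request_probability = unlist(g$lab_request_probability) %||% numeric(),
        lab_value_distribution = lapply(g$lab_value_distribution %||% list(),
                                        as.numeric),
        enrollment_years = as.numeric(unlist(g$enrollment_years)),
        exclusion_code_probability = g$exclusion_code_probability %||% 0,
        ambiguous_code_probability = g$ambiguous_code_probability %||% 0,
        diagnosis_date_offset_years =
          if (is.null(g$diagnosis_date_offset_years)) NULL
          else as.numeric(unlist(g$diagnosis_date_offset_years))
      )
    })
  }
  list(profiles = profiles, run_date = cfg$run_date, seed = cfg$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
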