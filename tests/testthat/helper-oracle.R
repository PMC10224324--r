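# Independent brute-force scorer. Re-reads the shipped rule-set YAML with
# yaml::read_yaml (not load_ruleset) and evaluates every rule by explicit
# per-event date arithmetic, as a reference for the scoring engine.

oracle_config <- function(path = system.file("extdata", "pad_ruleset.yaml",
                                             package = "padscreen")) {
  yaml::read_yaml(path)
}

oracle_age <- function(birth, ref) {
  # whole years completed at ref under the anniversary convention
  age <- as.integer(format(ref, "%Y")) - as.integer(format(birth, "%Y"))
  if (format(ref, "%m-%d") < format(birth, "%m-%d")) age <- age - 1L
  age
}

oracle_score <- function(record, run_date, cfg = oracle_config()) {
  run_date <- as.Date(run_date)
  amb_codes <- vapply(cfg$ambiguous, `[[`, "", "icpc_code")
  exc_codes <- vapply(cfg$exclusions, `[[`, "", "icpc_code")

  # censoring: earliest ambiguous diagnosis on/before the run date
  censor <- run_date
  for (j in seq_len(nrow(record$diagnoses))) {
    d <- record$diagnoses[j, ]
    if (d$icpc_code %in% amb_codes && d$date <= run_date && d$date < censor) {
      censor <- d$date
    }
  }

  # eligibility on the untruncated record
  for (j in seq_len(nrow(record$diagnoses))) {
    if (record$diagnoses$icpc_code[j] %in% exc_codes) {
      return(list(eligible = FALSE, total = NA_real_, censoring_date = censor))
    }
  }
  age <- oracle_age(record$birth_date, censor)
  if (age < cfg$age_bounds$min || age > cfg$age_bounds$max) {
    return(list(eligible = FALSE, total = NA_real_, censoring_date = censor))
  }

  # antibiotics
  ab_w <- setNames(vapply(cfg$antibiotics, `[[`, 0, "weight"),
                   vapply(cfg$antibiotics, `[[`, "", "atc_code"))
  six <- as.POSIXlt(record$birth_date)
  six$year <- six$year + cfg$antibiotic_min_age_years
  six <- as.Date(six)
  win <- cfg$antibiotic_window_years * 365
  ab_sum <- 0
  for (j in seq_len(nrow(record$prescriptions))) {
    p <- record$prescriptions[j, ]
    if (p$atc_code %in% names(ab_w) &&
        p$date > censor - win && p$date <= censor && p$date >= six) {
      ab_sum <- ab_sum + ab_w[[p$atc_code]]
    }
  }
  enroll_end <- if (is.na(record$enrollment_end)) censor
                else min(censor, record$enrollment_end)
  days_enrolled <- as.numeric(enroll_end - record$enrollment_start)
  if (days_enrolled < win) {
    ab_sum <- ab_sum * cfg$antibiotic_window_years / (days_enrolled / 365)
  }

  # diagnosis categories, presence semantics
  icpc_sum <- 0
  for (cat_name in names(cfg$icpc_categories)) {
    w <- cfg$windows[[cat_name]]
    win_days <- if (identical(w, "lifetime")) Inf else w * 365
    for (rule in cfg$icpc_categories[[cat_name]]) {
      fired <- FALSE
      for (j in seq_len(nrow(record$diagnoses))) {
        d <- record$diagnoses[j, ]
        if (d$icpc_code %in% unlist(rule$codes) &&
            d$date <= censor && d$date > censor - win_days) {
          fired <- TRUE
        }
      }
      if (fired) icpc_sum <- icpc_sum + rule$weight
    }
  }

  # labs, strict inequality, any time up to the censoring date
  lab_sum <- 0
  for (rule in cfg$labs) {
    fired <- FALSE
    for (j in seq_len(nrow(record$labs))) {
      l <- record$labs[j, ]
      if (l$analyte == rule$analyte && l$date <= censor &&
          l$value < rule$threshold) {
        fired <- TRUE
      }
    }
    if (fired) lab_sum <- lab_sum + rule$weight
  }

  # visits in the year before the censoring date
  n_visits <- 0
  for (j in seq_len(nrow(record$visits))) {
    v <- record$visits[j, ]
    if (v$date > censor - cfg$visits$window_days && v$date <= censor) {
      n_visits <- n_visits + 1
    }
  }
  visit_sum <- if (n_visits >= cfg$visits$cutoff) cfg$visits$weight else 0

  list(eligible = TRUE, censoring_date = censor,
       antibiotic = ab_sum, icpc = icpc_sum, lab = lab_sum,
       visits = visit_sum,
       total = ab_sum + icpc_sum + lab_sum + visit_sum)
}
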