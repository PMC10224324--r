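# Shared fixture builders. The pinned run date matches the extraction date
# used throughout the package's examples.
RUN_DATE <- as.Date("2021-11-18")

# An adult with full (>= 4 year) enrollment and no events unless given.
make_record <- function(patient_id = "p1",
                        birth_date = "1980-06-15",
                        enrollment_start = "2000-01-01",
                        enrollment_end = NA,
                        ...) {
  patient_record(patient_id = patient_id, birth_date = birth_date,
                 sex = "F", enrollment_start = enrollment_start,
                 enrollment_end = enrollment_end, ...)
}

dx <- function(codes, dates) data.frame(icpc_code = codes, date = dates)
rx <- function(codes, dates) data.frame(atc_code = codes, date = dates)
lab <- function(analytes, values, dates) {
  data.frame(analyte = analytes, value = values, date = dates)
}
vis <- function(dates, modality = "physical") {
  data.frame(date = dates, modality = modality)
}

# n visit dates inside the year before `end`.
visit_dates <- function(n, end = RUN_DATE) {
  format(end - seq_len(n) * 10)
}

# Write a cohort of records to a temp dir and return the dir.
cohort_dir_of <- function(records) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  cohort <- structure(setNames(records,
                               vapply(records, `[[`, "", "patient_id")),
                      class = "pad_cohort")
  write_cohort(cohort, dir)
  dir
}

# Random small record drawing codes from the rule set plus ambiguous,
# exclusion and unrelated codes; used by the oracle-equivalence and
# property suites.
random_record <- function(i, ruleset = default_ruleset()) {
  set.seed(20000 + i)
  birth <- RUN_DATE - round(runif(1, 5, 80) * 365.25)
  start <- birth + 30
  code_pool <- c(unlist(ruleset$icpc$codes), ruleset$ambiguous$icpc_code,
                 ruleset$exclusions$icpc_code, "Z99", "A00", "K01.01")
  atc_pool <- c(ruleset$antibiotics$atc_code, "J01XX01", "N02BE01")
  n_dx <- sample(0:12, 1)
  n_rx <- sample(0:12, 1)
  n_lab <- sample(0:6, 1)
  n_vis <- sample(0:15, 1)
  rand_dates <- function(n) birth + 365 + floor(runif(n) * as.numeric(RUN_DATE - birth - 365))
  analyte_pool <- setdiff(lab_analytes(), c("total_protein", "albumin"))
  make_record(
    patient_id = sprintf("rnd_%03d", i),
    birth_date = birth,
    enrollment_start = start,
    enrollment_end = if (runif(1) < 0.2) RUN_DATE - sample(0:400, 1) else NA,
    diagnoses = if (n_dx > 0)
      dx(sample(code_pool, n_dx, replace = TRUE), rand_dates(n_dx)),
    prescriptions = if (n_rx > 0)
      rx(sample(atc_pool, n_rx, replace = TRUE), rand_dates(n_rx)),
    labs = if (n_lab > 0)
      lab(sample(analyte_pool, n_lab, replace = TRUE),
          round(runif(n_lab, 0, 30), 2), rand_dates(n_lab)),
    visits = if (n_vis > 0)
      vis(rand_dates(n_vis),
          sample(c("physical", "electronic"), n_vis, replace = TRUE))
  )
}
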