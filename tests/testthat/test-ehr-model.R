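test_that("code normalization trims, upper-cases and is idempotent", {
  expect_equal(normalize_icpc(" r75.01 "), "R75.01")
  expect_equal(normalize_atc(" j01ca04"), "J01CA04")
  codes <- c("r81", " D94.02", "T99.01 ")
  expect_equal(normalize_icpc(normalize_icpc(codes)), normalize_icpc(codes))
  expect_error(normalize_icpc("R8", strict = TRUE), "Invalid ICPC")
  expect_error(normalize_atc("J01CA4", strict = TRUE), "Invalid ATC")
})

test_that("age follows the birthday-anniversary convention", {
  b <- as.Date("2000-06-15")
  expect_equal(age_at(b, as.Date("2012-06-14")), 11L)
  expect_equal(age_at(b, as.Date("2012-06-15")), 12L)
  expect_equal(age_at(b, as.Date("2012-12-31")), 12L)
})

test_that("calculated globulin is total protein minus albumin", {
  expect_equal(compute_calculated_globulin(70, 45), 25)
  # 17 g/L sits below the 18 g/L scoring threshold
  expect_equal(compute_calculated_globulin(60, 43), 17)
  for (x in c(0, 13.7, 60)) {
    expect_equal(compute_calculated_globulin(x, x), 0)
  }
  # exact complement identity
  p <- runif(20, 55, 90); a <- runif(20, 20, 50)
  expect_identical(compute_calculated_globulin(p, a) + a, p)
  expect_warning(compute_calculated_globulin(40, 45), "physiologically impossible")
  expect_error(compute_calculated_globulin(-1, 0), "non-negative")
})

test_that("load_cohort attaches sorted streams to the right patients", {
  dir <- withr::local_tempdir()
  writeLines(c("patient_id,birth_date,sex,enrollment_start,enrollment_end",
               "a,1980-01-01,F,2000-01-01,",
               "b,1990-05-05,M,2010-01-01,2021-01-01",
               "c,1975-12-31,F,1995-06-01,"),
             file.path(dir, "patients.csv"))
  writeLines(c("patient_id,icpc_code,date",
               "b,r81,2020-03-01",
               "b, r75.01 ,2018-01-01"),
             file.path(dir, "diagnoses.csv"))
  writeLines(c("patient_id,atc_code,date", "a,j01ca04,2019-07-01"),
             file.path(dir, "prescriptions.csv"))
  writeLines("patient_id,analyte,value_g_per_l,date", file.path(dir, "labs.csv"))
  writeLines(c("patient_id,date,modality", "c,2021-02-01,telephone"),
             file.path(dir, "visits.csv"))

  cohort <- load_cohort(dir)
  expect_length(cohort, 3)
  expect_equal(names(cohort), c("a", "b", "c"))
  expect_equal(cohort$b$diagnoses$icpc_code, c("R75.01", "R81"))  # sorted, normalized
  expect_equal(cohort$b$diagnoses$date, as.Date(c("2018-01-01", "2020-03-01")))
  expect_equal(cohort$a$prescriptions$atc_code, "J01CA04")
  expect_equal(nrow(cohort$a$diagnoses), 0)
  expect_equal(cohort$c$visits$modality, "electronic")  # telephone mapped
  expect_true(is.na(cohort$a$enrollment_end))
  expect_equal(cohort$b$enrollment_end, as.Date("2021-01-01"))
})

test_that("one patient with empty event tables gives four empty streams", {
  dir <- withr::local_tempdir()
  writeLines(c("patient_id,birth_date,sex,enrollment_start,enrollment_end",
               "solo,1980-01-01,unknown,2000-01-01,"),
             file.path(dir, "patients.csv"))
  writeLines("patient_id,icpc_code,date", file.path(dir, "diagnoses.csv"))
  writeLines("patient_id,atc_code,date", file.path(dir, "prescriptions.csv"))
  writeLines("patient_id,analyte,value_g_per_l,date", file.path(dir, "labs.csv"))
  writeLines("patient_id,date,modality", file.path(dir, "visits.csv"))
  cohort <- load_cohort(dir)
  expect_length(cohort, 1)
  rec <- cohort$solo
  expect_equal(nrow(rec$diagnoses), 0)
  expect_equal(nrow(rec$prescriptions), 0)
  expect_equal(nrow(rec$labs), 0)
  expect_equal(nrow(rec$visits), 0)
})

test_that("loader rejects schema errors, bad dates and orphan events", {
  dir <- withr::local_tempdir()
  writeLines(c("patient_id,birth_date,sex,enrollment_start,enrollment_end",
               "a,1980-01-01,F,2000-01-01,"), file.path(dir, "patients.csv"))
  writeLines(c("patient_id,icpc_code,date", "a,R81,2020-01-01"),
             file.path(dir, "diagnoses.csv"))
  writeLines("patient_id,atc_code,date", file.path(dir, "prescriptions.csv"))
  writeLines("patient_id,analyte,value_g_per_l,date", file.path(dir, "labs.csv"))
  writeLines("patient_id,date,modality", file.path(dir, "visits.csv"))

  # missing column
  writeLines(c("patient_id,code,date", "a,R81,2020-01-01"),
             file.path(dir, "diagnoses.csv"))
  expect_error(load_cohort(dir), "icpc_code")
  # unparseable date
  writeLines(c("patient_id,icpc_code,date", "a,R81,01/02/2020"),
             file.path(dir, "diagnoses.csv"))
  expect_error(load_cohort(dir), "Unparseable date")
  # orphan patient id
  writeLines(c("patient_id,icpc_code,date", "ghost,R81,2020-01-01"),
             file.path(dir, "diagnoses.csv"))
  expect_error(load_cohort(dir), "ghost")
})

test_that("calculated globulin is derived when protein and albumin share a date", {
  rec <- make_record(labs = lab(c("total_protein", "albumin", "total_protein"),
                                c(60, 43, 70),
                                c("2020-01-01", "2020-01-01", "2021-01-01")))
  cg <- rec$labs[rec$labs$analyte == "calculated_globulin", ]
  expect_equal(nrow(cg), 1)  # only the shared-date pair is derived
  expect_equal(cg$value, 17)
  expect_equal(cg$date, as.Date("2020-01-01"))
  # a stored result on the shared date suppresses derivation
  rec2 <- make_record(labs = lab(
    c("total_protein", "albumin", "calculated_globulin"),
    c(60, 43, 16.5), rep("2020-01-01", 3)))
  cg2 <- rec2$labs[rec2$labs$analyte == "calculated_globulin", ]
  expect_equal(cg2$value, 16.5)
})

test_that("cohort write/load round trip reproduces records exactly", {
  rec1 <- make_record("r1",
    diagnoses = dx(c("R81", "D94.02"), c("2020-03-01", "2015-06-15")),
    prescriptions = rx("J01CA04", "2019-01-01"),
    labs = lab("IgA_total", 0.65, "2018-02-02"),
    visits = vis(c("2021-05-01", "2021-06-01"), c("physical", "electronic")))
  rec2 <- make_record("r2", enrollment_end = "2021-01-01")
  dir <- withr::local_tempdir()
  cohort <- structure(list(r1 = rec1, r2 = rec2), class = "pad_cohort")
  write_cohort(cohort, dir)
  back <- load_cohort(dir)
  for (id in c("r1", "r2")) {
    for (f in c("patient_id", "birth_date", "sex", "enrollment_start",
                "enrollment_end", "diagnoses", "prescriptions", "labs",
                "visits")) {
      expect_equal(back[[id]][[f]], cohort[[id]][[f]],
                   ignore_attr = TRUE, label = paste(id, f))
    }
  }
})

test_that("write_results has the fixed column contract", {
  # empty input -> header-only file
  path <- withr::local_tempfile(fileext = ".csv")
  write_results(list(), path)
  hdr <- readLines(path)
  expect_length(hdr, 1)
  expect_match(hdr, "^patient_id,censoring_date,eligible,exclusion_reason")

  eligible <- score_patient(
    make_record(diagnoses = dx("R81", "2020-05-01")), RUN_DATE)
  excluded <- score_patient(
    make_record("px", diagnoses = dx("T99.01", "2010-01-01")), RUN_DATE)
  write_results(list(eligible, excluded), path)
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(tbl), 2)
  row1 <- tbl[tbl$patient_id == "p1", ]
  expect_true(row1$eligible)
  sub <- row1$antibiotic_score + row1$respiratory_tract_infections +
    row1$gastro_intestinal + row1$other_infections + row1$auto_immune +
    row1$malignancy_lymphoproliferative_other + row1$lab_score + row1$visit_score
  expect_equal(sub, row1$total_score)
  row2 <- tbl[tbl$patient_id == "px", ]
  expect_false(row2$eligible)
  expect_true(is.na(row2$total_score))
  expect_equal(row2$exclusion_reason, "exclusion_code")
})
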