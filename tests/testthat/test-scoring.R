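rs <- default_ruleset()

test_that("antibiotic score sums weights over in-window prescriptions", {
  expect_equal(antibiotic_score(make_record(), RUN_DATE, rs), 0)

  # full enrollment (>= 1460 days): no correction factor
  rec <- make_record(
    enrollment_start = format(RUN_DATE - 1460),
    prescriptions = rx(c("J01CA04", "J01CA04", "J01CA04", "J01MA02"),
                       c("2021-01-01", "2020-06-01", "2019-02-01", "2018-06-01")))
  expect_equal(antibiotic_score(rec, RUN_DATE, rs), 3 * 2 + 1)

  # short enrollment: weighted sum scaled by 4 / (days/365)
  rec2 <- make_record(
    enrollment_start = format(RUN_DATE - 730),
    prescriptions = rx(c("J01AA02", "J01AA02"), c("2021-01-01", "2021-05-01")))
  expect_equal(antibiotic_score(rec2, RUN_DATE, rs), 4 * 4 / (730 / 365))

  # non-listed antibiotic and out-of-window prescriptions score nothing
  rec3 <- make_record(prescriptions = rx(
    c("N02BE01", "J01CA04"), c("2021-01-01", format(RUN_DATE - 1461))))
  expect_equal(antibiotic_score(rec3, RUN_DATE, rs), 0)
})

test_that("prescriptions before the sixth birthday never count", {
  run <- as.Date("2010-06-01")
  rec <- make_record(birth_date = "2003-01-01", enrollment_start = "2003-01-01",
                     prescriptions = rx(c("J01CA04", "J01CA04"),
                                        c("2008-06-01", "2009-06-01")))
  # only the prescription after 2009-01-01 (6th birthday) counts
  expect_equal(antibiotic_score(rec, run, rs), 2)
})

test_that("no observable enrollment before censoring is an error", {
  rec <- make_record(enrollment_start = format(RUN_DATE + 10))
  expect_error(antibiotic_score(rec, RUN_DATE, rs), "enrollment")
})

test_that("diagnosis categories use presence semantics and their windows", {
  rec <- make_record(diagnoses = dx("R81", "2020-05-01"))
  expect_equal(icpc_category_score(rec, RUN_DATE, "respiratory_tract_infections", rs), 3)

  # duplicated code counts once; different codes add up
  rec2 <- make_record(diagnoses = dx(c("R75.01", "R75.01", "R81"),
                                     c("2018-01-01", "2020-01-01", "2021-01-01")))
  expect_equal(icpc_category_score(rec2, RUN_DATE, "respiratory_tract_infections", rs),
               2 + 3)

  # 11 years back is outside the 10-year respiratory window
  rec3 <- make_record(diagnoses = dx("R81", format(RUN_DATE - 11 * 365)))
  expect_equal(icpc_category_score(rec3, RUN_DATE, "respiratory_tract_infections", rs), 0)

  # lifetime window: auto-immune code 30 years back still scores
  rec4 <- make_record(birth_date = "1960-01-01", enrollment_start = "1985-01-01",
                      diagnoses = dx("D94.02", format(RUN_DATE - 30 * 365)))
  expect_equal(icpc_category_score(rec4, RUN_DATE, "auto_immune", rs), 2)

  expect_error(icpc_category_score(rec, RUN_DATE, "nope", rs), "category")
})

test_that("either Hodgkin code fires the merged component exactly once", {
  for (codes in list("B72", "B72.01", c("B72", "B72.01"))) {
    rec <- make_record(diagnoses = dx(codes, rep("2021-06-01", length(codes))))
    res <- score_patient(rec, RUN_DATE, rs)
    # censored at the (ambiguous) Hodgkin date, which still scores itself
    expect_equal(res$category_scores[["malignancy_lymphoproliferative_other"]], 1,
                 label = paste(codes, collapse = "+"))
  }
})

test_that("lab rules are strict-inequality, once per analyte, any time", {
  rec <- make_record(labs = lab("IgG_total", 6.5, "2010-01-01"))
  expect_equal(lab_score(rec, RUN_DATE, rs), 8)

  rec2 <- make_record(labs = lab(c("IgA_total", "calculated_globulin"),
                                 c(0.5, 17), c("2015-01-01", "2012-01-01")))
  expect_equal(lab_score(rec2, RUN_DATE, rs), 4 + 6)

  # exactly at threshold does not score
  rec3 <- make_record(labs = lab("IgG_total", 7, "2015-01-01"))
  expect_equal(lab_score(rec3, RUN_DATE, rs), 0)

  # repeated low values score once
  rec4 <- make_record(labs = lab(rep("IgM_total", 3), c(0.1, 0.2, 0.3),
                                 c("2010-01-01", "2015-01-01", "2020-01-01")))
  expect_equal(lab_score(rec4, RUN_DATE, rs), 8)
})

test_that("visit criterion is >= 6 visits in the 365-day window", {
  expect_equal(visit_score(make_record(visits = vis(visit_dates(6))), RUN_DATE, rs), 3)
  expect_equal(visit_score(make_record(visits = vis(visit_dates(5))), RUN_DATE, rs), 0)
  # 10 visits of which 7 outside the window
  dates <- c(visit_dates(3), format(RUN_DATE - 400 - seq_len(7) * 10))
  expect_equal(visit_score(make_record(visits = vis(dates)), RUN_DATE, rs), 0)
  # both modalities count
  recm <- make_record(visits = vis(visit_dates(6),
                                   rep(c("physical", "electronic"), 3)))
  expect_equal(visit_score(recm, RUN_DATE, rs), 3)
})

test_that("score_patient composes the verified subscores", {
  expect_equal(score_patient(make_record(), RUN_DATE, rs)$total_score, 0)

  rec <- make_record(
    diagnoses = dx("R81", "2020-05-01"),
    prescriptions = rx(c("J01CA04", "J01CA04"), c("2020-01-01", "2021-01-01")),
    visits = vis(visit_dates(7)))
  res <- score_patient(rec, RUN_DATE, rs)
  expect_equal(res$antibiotic_score, 4)
  expect_equal(res$category_scores[["respiratory_tract_infections"]], 3)
  expect_equal(res$visit_score, 3)
  expect_equal(res$total_score, 10)

  # ineligible: cystic fibrosis exclusion
  resx <- score_patient(
    make_record(diagnoses = dx("T99.10", "2010-01-01")), RUN_DATE, rs)
  expect_false(resx$eligibility$eligible)
  expect_true(is.na(resx$total_score))
})

test_that("total decomposes into subscores and fired components", {
  for (i in 1:25) {
    rec <- random_record(i)
    res <- score_patient(rec, RUN_DATE, rs)
    if (!res$eligibility$eligible) next
    expect_equal(res$total_score,
                 res$antibiotic_score + sum(res$category_scores) +
                   res$lab_score + res$visit_score,
                 tolerance = 1e-12)
    expect_equal(sum(res$fired_components$points), res$total_score,
                 tolerance = 1e-12)
    expect_true(all(res$fired_components$component_id %in% component_ids(rs)))
  }
})

test_that("duplicating a diagnosis never changes category scores", {
  for (i in 1:10) {
    rec <- random_record(i)
    if (nrow(rec$diagnoses) == 0) next
    dup <- rec$diagnoses[sample(nrow(rec$diagnoses), 1), ]
    rec2 <- make_record(patient_id = rec$patient_id, birth_date = rec$birth_date,
                        enrollment_start = rec$enrollment_start,
                        enrollment_end = rec$enrollment_end,
                        diagnoses = rbind(rec$diagnoses, dup),
                        prescriptions = rec$prescriptions,
                        labs = rec$labs, visits = rec$visits)
    r1 <- score_patient(rec, RUN_DATE, rs)
    r2 <- score_patient(rec2, RUN_DATE, rs)
    expect_equal(r2$category_scores, r1$category_scores)
    expect_equal(r2$total_score, r1$total_score)
  }
})

test_that("appending one in-window prescription raises the score by its weight", {
  rec <- make_record(
    enrollment_start = format(RUN_DATE - 4000),
    prescriptions = rx("J01CA04", "2021-01-01"))
  base <- score_patient(rec, RUN_DATE, rs)$antibiotic_score
  for (atc in c("J01CA04", "J01MA02", "S02AA16")) {
    w <- rs$antibiotics$weight[rs$antibiotics$atc_code == atc]
    rec2 <- make_record(
      enrollment_start = format(RUN_DATE - 4000),
      prescriptions = rbind(rec$prescriptions,
                            data.frame(atc_code = atc, date = as.Date("2021-03-01"))))
    expect_equal(score_patient(rec2, RUN_DATE, rs)$antibiotic_score, base + w)
  }
})

test_that("enrollment of exactly 1460 days leaves the antibiotic sum uncorrected", {
  raw <- make_record(
    enrollment_start = format(RUN_DATE - 5000),
    prescriptions = rx(c("J01CA04", "J01AA02"), c("2021-01-01", "2020-01-01")))
  exact <- make_record(
    enrollment_start = format(RUN_DATE - 1460),
    prescriptions = raw$prescriptions)
  expect_equal(antibiotic_score(exact, RUN_DATE, rs),
               antibiotic_score(raw, RUN_DATE, rs))
})

test_that("screen_cohort ranks, breaks ties by id, and flags deterministically", {
  mk <- function(id, n_rx) {
    make_record(patient_id = id,
                prescriptions = if (n_rx > 0)
                  rx(rep("J01CA04", n_rx),
                     format(RUN_DATE - seq_len(n_rx) * 30)))
  }
  cohort <- list(mk("z_low", 0), mk("a_mid", 2), mk("m_high", 5), mk("b_mid", 2))
  set <- screen_cohort(cohort, RUN_DATE, rs, threshold = 5)
  expect_equal(set$table$patient_id, c("m_high", "a_mid", "b_mid", "z_low"))
  expect_equal(set$flagged, "m_high")

  set2 <- screen_cohort(cohort, RUN_DATE, rs, top_k = 2)
  expect_equal(set2$flagged, c("m_high", "a_mid"))

  # all-zero cohort, top-k = 5 flags everyone at score 0
  zeros <- lapply(letters[1:5], function(id) mk(id, 0))
  set3 <- screen_cohort(zeros, RUN_DATE, rs, top_k = 5)
  expect_length(set3$flagged, 5)
  expect_true(all(set3$table$total_score == 0))

  # determinism on repeat
  set4 <- screen_cohort(cohort, RUN_DATE, rs, threshold = 5)
  expect_identical(set4$table, set$table)

  # ineligible patients are listed unranked
  cohort5 <- c(cohort, list(make_record(patient_id = "x_excl",
                                        diagnoses = dx("B73", "2001-01-01"))))
  set5 <- screen_cohort(cohort5, RUN_DATE, rs, top_k = 1)
  expect_true(is.na(set5$table$rank[set5$table$patient_id == "x_excl"]))
  expect_error(screen_cohort(cohort, RUN_DATE, rs), "exactly one")
})

test_that("explain_result lists each fired component with its points", {
  rec <- make_record(diagnoses = dx("R81", "2020-05-01"),
                     labs = lab("IgA_total", 0.5, "2019-01-01"))
  res <- score_patient(rec, RUN_DATE, rs)
  ex <- explain_result(res)
  expect_setequal(ex$component_id, c("icpc:R81", "lab:IgA_total"))
  expect_equal(sum(ex$points), res$total_score)
})
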