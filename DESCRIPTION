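Package: padscreen
Title: Rule-Based Screening for Primary Antibody Deficiency in Primary Care EHR Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a weighted, time-windowed screening score for early
    detection of primary antibody deficiency (PAD) from structured primary care
    electronic health records: coded diagnoses (ICPC), antibiotic prescriptions
    (ATC), immunoglobulin and calculated-globulin laboratory results, and GP
    visit counts. Provides the published rule set as a machine-readable default,
    censoring-date and eligibility logic, the component-selection statistics
    used during development (sensitivity, specificity, Youden's index, cut-off
    sweeps, group summaries, concordance), and a calibrated synthetic cohort
    generator so every stage can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
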