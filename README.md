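# padscreen

Rule-based screening for **primary antibody deficiency (PAD)** in structured
primary-care EHR data.

PAD — common variable immunodeficiency, IgG subclass deficiency, selective
IgA deficiency and related disorders of immunoglobulin production — presents
heterogeneously (recurrent respiratory and gastro-intestinal infections,
auto-immune phenomena, lymphoproliferation) and is rare, so diagnosis is
typically delayed by many years. Because general practitioners in gatekeeper
health systems hold a near-complete coded record of each patient,
a weighted screening score over that record can surface patients in whom
immunoglobulin testing should be considered. `padscreen` implements such a
score as a reusable rule engine, together with the component-selection
statistics used during its development and a calibrated synthetic cohort
generator, so that every stage can be developed and tested without access to
patient data. It is aimed at clinical-informatics researchers and
epidemiologists working with coded primary-care extracts (ICPC diagnoses,
ATC prescriptions, laboratory results, visit counts).

## The score

For a patient with censoring date $t_c$ (the data-extraction date, or the
date of an earlier "ambiguous" diagnosis such as lymphoma that can itself
cause secondary antibody deficiency), the risk score is

$$
S \;=\; \underbrace{f \cdot \sum_{p \,\in\, \mathrm{Rx}(t_c-4\mathrm{y},\,t_c]} w_{\mathrm{ATC}(p)}}_{\text{antibiotics}}
\;+\; \underbrace{\sum_{c} w_c\,\mathbb{1}\{c \text{ coded in window}_c\}}_{\text{diagnoses, 5 categories}}
\;+\; \underbrace{\sum_{a} w_a\,\mathbb{1}\{\exists\, \text{result} < \theta_a\}}_{\text{laboratory}}
\;+\; \underbrace{3\cdot\mathbb{1}\{\#\mathrm{visits}(t_c-1\mathrm{y},\,t_c] \ge 6\}}_{\text{visits}}
$$

where each antibiotic prescription contributes its ATC-specific weight
(repeats accumulate), $f = 4/(\text{days enrolled}/365)$ when the patient is
enrolled less than four years (else $f = 1$) and prescriptions before the
sixth birthday never count; diagnosis components use presence semantics with
a 10-year window for respiratory-tract-infection and gastro-intestinal codes
and a lifetime window for other infections, auto-immune and
malignancy/lymphoproliferative codes; laboratory thresholds $\theta_a$ are
strict (IgG < 7 g/L, ..., calculated globulin < 18 g/L). The default rule
set has **106 scored components**, ships as a machine-readable YAML file,
and is reproduced by `default_ruleset()`. Patients are excluded from
screening if any of 14 exclusion codes (markers of secondary antibody
deficiency) appears anywhere in their record, or if they are under 12 or
over 70 years old at the censoring date.

## Worked example

```r
library(padscreen)

rec <- patient_record(
  patient_id = "example-01", birth_date = "1985-03-10", sex = "F",
  enrollment_start = "2006-01-01",
  diagnoses = data.frame(icpc_code = c("R81", "R75.02", "D11"),
                         date = c("2020-02-11", "2018-09-03", "2016-05-20")),
  prescriptions = data.frame(atc_code = c("J01CA04", "J01CA04", "J01AA02"),
                             date = c("2021-01-15", "2020-03-02", "2019-11-27")),
  labs = data.frame(analyte = c("total_protein", "albumin"),
                    value = c(60, 43), date = "2019-06-01"),
  visits = data.frame(date = format(as.Date("2021-11-01") - 30 * (0:6)),
                      modality = "physical"))

res <- score_patient(rec, run_date = "2021-11-18")
res
#> <pad_screening_result> example-01
#>   censoring date: 2021-11-18 ( run_date )
#>   antibiotic: 6 | labs: 6 | visits: 3
#>    respiratory_tract_infections : 5
#>    gastro_intestinal : 2
#>   TOTAL: 22
```

Reading the output: two amoxicillin (J01CA04, weight 2 each) and one
doxycycline (J01AA02, weight 2) prescription inside the 4-year window give
the antibiotic block 6; pneumonia (R81, 3) and chronic rhinosinusitis
(R75.02, 2) fire in the respiratory category and diarrhea (D11, 2) in the
gastro-intestinal one; the total-protein/albumin pair on one date yields a
calculated globulin of 17 g/L, below the 18 g/L threshold (6 points); and
seven GP visits in the last year reach the ≥ 6 cut-off (3 points), for a
total of 22. `explain_result(res)` tabulates exactly this decomposition,
one row per fired component.

Cohort-level work goes through `load_cohort()` / `screen_cohort()` /
`write_results()`, or through the shell front end:

```sh
Rscript inst/scripts/padscreen simulate --config sim.yaml --out-dir study/
Rscript inst/scripts/padscreen screen --cohort study/general --out-dir out/ --top-k 10
Rscript inst/scripts/padscreen evaluate --pad study/pad --pcid study/pc_immunodef \
    --control study/general --out-dir eval/
```

`default_profiles()` provides seven calibrated synthetic group profiles
(general population, upper-RTI, COPD/asthma, IBD, malignancy, primary-care
immunodeficiency, PAD); `youden_index()`, `cutoff_sweep()`,
`group_summary()` and `concordance()` reproduce the component-selection
machinery. See the methods vignette (`vignettes/pad-screening-methods.Rmd`)
for the full model description and design rationale.

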