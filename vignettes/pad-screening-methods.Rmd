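---
title: "Screening for primary antibody deficiency in coded primary-care records: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for primary antibody deficiency in coded primary-care records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(padscreen)
```

## The screening problem

Primary antibody deficiencies (PAD) are rare, heterogeneous disorders of
immunoglobulin production. Their presenting picture — recurrent upper and
lower respiratory tract infections, gastro-intestinal complaints,
auto-immune phenomena, lymphoproliferative signs — is individually common in
primary care, which is why diagnosis is routinely delayed by many years
while effective replacement therapy exists. In a gatekeeper system the GP
record is close to a complete longitudinal account of a patient's contacts,
coded with ICPC diagnoses and ATC prescriptions. `padscreen` operationalises
a weighted screening score over exactly those structured elements, so that
it can run automatically over an EHR extract and rank patients for
immunoglobulin testing. Free text is deliberately out of scope: every input
the engine consumes is a code, a number or a date.

## The score and its semantics

A patient's record is evaluated at a **censoring date**. By default this is
the run (extraction) date; if the record contains an *ambiguous* diagnosis —
one that may be a PAD complication but can equally cause secondary antibody
deficiency (Hodgkin and non-Hodgkin lymphoma, gastric and colorectal cancer,
post-transplantation state) — the earliest such diagnosis becomes the
censoring date and only the record up to it is scored. Events dated exactly
on the censoring date are **included**: several ambiguous codes are
themselves weighted components, and an exclusive cut would make those
weights unreachable.

Eligibility is checked before scoring. Fourteen exclusion codes (leukemia,
multiple myeloma, HIV/AIDS, substance-abuse and eating-disorder codes, an
existing immunodeficiency code, cystic fibrosis) mark patients in whom a low
immunoglobulin result would most likely be secondary; any occurrence at any
date excludes. We screen exclusions on the *untruncated* record — an
exclusion diagnosis recorded after an ambiguous-diagnosis censoring date
still excludes, since it identifies secondary antibody deficiency regardless
of its timing relative to the censoring window. Age must be 12–70 years *at
the censoring date* (the moment the algorithm would fire); both bounds are
inclusive, with age counted in completed years under the ordinary
birthday-anniversary convention.

The score itself has four blocks:

* **Antibiotics.** Each prescription of one of 20 listed antibiotics inside
  the 4-year window before the censoring date contributes its ATC-specific
  weight (0.5–2); repeats accumulate. If the patient has been enrolled less
  than 4 × 365 days before the censoring date, the weighted sum is scaled by
  `4 / (days_enrolled / 365)`. The published correction is phrased in terms
  of the prescription *count*; we apply it to the weighted sum, which is
  identical by linearity (scale each antibiotic's count, then weight). It is
  applied only below the 4-year enrollment mark, and we log a warning below
  90 enrolled days, where the extrapolation becomes unstable, without
  capping the multiplier. Prescriptions before the sixth birthday never
  count; with the default 12-year age floor and a 4-year window this rule is
  unreachable, but it keeps the rule set correct if windows are
  reconfigured.
* **Diagnosis categories.** 77 weighted ICPC components in five categories,
  with presence semantics: a component contributes its weight at most once,
  however often its code recurs. Respiratory-tract-infection and
  gastro-intestinal codes are sought in the 10 years before the censoring
  date; other infections, auto-immune and malignancy/lymphoproliferative
  codes over the whole record. Parent and sub-codes (R75, R75.01, R75.02)
  are independent components, as published.
* **Laboratory values.** Eight analytes with strict (<) thresholds in g/L;
  each fires at most once, from any result up to the censoring date.
  Calculated globulin (total protein − albumin) is derived automatically
  whenever a total-protein and an albumin result share a date and no stored
  calculated-globulin result exists on that date; we do not pair results
  across dates, which would invent a temporal join the data do not support.
* **Visits.** Three points when the patient had ≥ 6 GP visits — physical and
  electronic alike, with telephone consultations mapped to electronic at
  load time — in the 365 days before the censoring date.

All windows are half-open day windows `(censor − N days, censor]` with a
365-day year (1460, 3650, 365 days), matching the 365-day year inside the
enrollment correction and giving unambiguous leap-year behaviour.

Two editorial decisions about the published component table are built into
`default_ruleset()`. First, the table lists *B72 Hodgkin's disease* and
*B72.01 Hodgkin's disease* as separate rows with identical description and
weight; we merge them into one component that fires on either code, which
reconciles the enumerated table with the stated total of 106 components
(B72.02, non-Hodgkin lymphoma, remains separate). Second, the ambiguous-code
list contains a duplicated D74 row labelled "Colon or rectal cancer"
alongside "D74 Gastric cancer"; we record the colorectal entry under D75,
the standard ICPC-1 code for colorectal malignancy, and drop the literal
duplicate. Two respiratory components with debatable infection semantics
(R96 asthma, R90 tonsil/adenoid hypertrophy) are retained exactly as
published; fidelity to the table takes precedence over clinical
second-guessing.

No final high-risk cut-off on the total score is asserted: the intended use
is ranking (top-k) or a caller-chosen threshold, with the operating point
left to prospective evaluation.

## Development statistics

The component-selection machinery is reimplemented as first-class
operations. For a binary component, sensitivity is computed separately in
the confirmed-PAD and primary-care-immunodeficiency groups (censored at
their diagnosis dates, so only pre-diagnosis data count) and averaged;
specificity comes from the general-population controls; Youden's index is
`mean sensitivity + specificity − 1`. Count criteria (GP visits, test
requests) are selected by sweeping candidate cut-offs and maximising
Youden's index, ties resolved toward the smallest cut-off; when the caller
supplies no candidates we sweep the integer range `median(case counts) ± 3`,
clipped below at 1, since the published procedure says only that candidates
were spread around the case median. The structured record keeps no dedicated
test-request stream, so the two request-count features use laboratory result
events as their observable proxy. Group summaries reproduce the descriptive
comparisons: per-year prescription means over the 10 pre-censoring years
(bins aligned with the scoring windows), the 4-year mean total, the 1-year
visit median, and per-analyte laboratory means/SDs computed only over
patients that have at least one result, with `n = 0` reported otherwise.
Concordance between two binary registrations is the percentage of patients
on whom they agree, reported rounded to the integer with the raw value
alongside.

## What the synthetic generator emulates — and what it does not

The generator exists so that every stage of the engine can be exercised,
calibrated and regression-tested without patient data. Its seven default
profiles encode the study groups' coarse structure:

* Event counts are homogeneous Poisson *within each pre-censoring year*.
  The PAD-like profile ramps its antibiotic rate linearly over years −10
  to −1 — escalation concentrated toward diagnosis — normalised so the
  expected 4-year pre-diagnosis total is **5.14** prescriptions; the
  general-population profile is flat at an expected 4-year total of
  **0.48**. GP-visit rates of 6/year (PAD-like) and 2/year (general) give
  1-year medians of 6 and 2; the four confounder profiles (upper RTI,
  COPD/asthma, IBD, malignancy) interpolate both rates.
* Diagnosis-code prevalences seed each confounder group's defining codes
  with probability 1 (asthma → R96, etc.) and give the PAD-like profile the
  symptom-code mix observed in coded case records (e.g. pneumonia ≈ 0.37,
  gastro-intestinal complaints ≈ 0.57); remaining per-code prevalences are
  free parameters with conservative defaults, all exposed in the profile
  objects.
* Laboratory results are sparse by design: request probabilities are of the
  order seen in routine primary care (≈ 0.9 % of general-population
  patients with an IgA result, ≈ 0.4 % with a calculated globulin), with
  truncated-Gaussian values at unremarkable control-group levels. The
  PAD-like and immunodeficiency profiles generate *no* immunoglobulin
  results pre-diagnosis, mirroring their absence from real pre-diagnosis
  records.
* Case profiles draw a synthetic diagnosis date 0.5–5 years before the run
  date and generate all events relative to it, so pre-diagnosis censoring is
  exercised end to end; enrollment lengths are Gaussian (mean 15 y, SD 5 y,
  clipped at 1 y) and injected ambiguous/exclusion codes are placed inside
  the enrollment interval.

Equally important is what the generator does **not** model: correlation
between streams (no clustering of prescriptions around infection
diagnoses), within-patient rate heterogeneity, seasonality, enrollment gaps
from practice switches, and any realistic joint distribution of codes.
Passing calibration and separation tests on these cohorts therefore
demonstrates that the *engine* computes the intended statistics and that the
configured rates are recovered — it says nothing about the score's
discriminative performance on real patients, which requires prospective
data. Default group sizes are kept at case-study scale (e.g. 30 PAD-like,
26 immunodeficiency, a few hundred controls); the calibration-recovery
checks and the acceptance script regenerate the PAD-like and general
profiles at n = 2000, where the Monte-Carlo standard error of the 4-year
prescription mean is about 0.05, and the separation check screens 500
patients per group.

## Numerical and interface choices

Dates are ISO-8601 calendar dates throughout; the engine never uses
time-of-day. Scores are plain doubles; the decomposition invariant
(total = antibiotic + five categories + labs + visits, and equal to the sum
over fired components) holds to one floating-point rounding unit and is
asserted in the tests. Ranking ties are broken by patient id, ascending, so
repeated runs are byte-identical. The rule set round-trips through a strict
YAML schema (unknown keys rejected, overlapping ambiguous/exclusion sets
rejected, weights and thresholds validated); the shipped file equals the
built-in default. Every CLI run writes a manifest with the rule-set MD5
checksum, run date, seed and package version; simulation manifests contain
the full profile parameterisation and regenerate the study byte-identically.
Cohorts are read from five CSV tables with fail-fast validation: missing
columns, unparseable dates and event rows for unknown patients are all
errors that name the offending table, value or id. Degenerate inputs are
handled explicitly: empty cohorts and empty event streams are valid; a
patient with no observable enrollment before the censoring date is an error
(the enrollment correction would divide by zero or extrapolate from
nothing); negative calculated globulin is returned but flagged as a
data-quality warning.

## Known limitations

The engine assumes one contiguous enrollment interval per patient. The
exclusion-after-ambiguous ordering rule and the D75 colorectal
reinterpretation are documented choices on points the published material
leaves open. Immunoglobulin reference thresholds are fixed adult values;
no age- or assay-specific adjustment is attempted. The development
statistics reproduce the selection *machinery*, not the original cohort
values, which are functions of the source databases.
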