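#' @title The PAD screening rule set
#' @description
#' A `pad_ruleset` bundles everything the scoring engine needs: the weighted
#' antibiotic (ATC) table, the five categories of weighted diagnosis (ICPC)
#' components with their look-back windows, the immunoglobulin /
#' calculated-globulin laboratory thresholds, the GP-visit criterion, the
#' "ambiguous" codes that truncate a record at their first occurrence, the
#' exclusion codes that mark likely secondary antibody deficiency, and the
#' age bounds for screening eligibility.
#' @name pad_ruleset
NULL

#' Valid laboratory analytes
#' @return Character vector of recognised analyte names.
#' @export
lab_analytes <- function() {
  c("IgG_total", "IgG1", "IgG2", "IgG3", "IgG4", "IgM_total", "IgA_total",
    "calculated_globulin", "total_protein", "albumin")
}

#' Valid ICPC component categories
#' @return Character vector of the five category names.
#' @export
icpc_categories <- function() {
  c("respiratory_tract_infections", "gastro_intestinal", "other_infections",
    "auto_immune", "malignancy_lymphoproliferative_other")
}

icpc_rule_tbl <- function(category, codes, description, weight) {
  tibble::tibble(
    component_id = vapply(codes, paste, "", collapse = "/"),
    codes = lapply(codes, normalize_icpc, strict = TRUE),
    description = description,
    weight = as.numeric(weight),
    category = category
  )
}

#' The published default rule set
#'
#' Returns the complete screening algorithm as shipped: 20 antibiotic rules,
#' 77 diagnosis components (33 respiratory-tract-infection, 10
#' gastro-intestinal, 7 other-infection, 16 auto-immune and 11 malignancy /
#' lymphoproliferative components — the two identically weighted Hodgkin's
#' disease codes B72 and B72.01 form a single merged component), 8 laboratory
#' rules, and the >= 6 visits/year criterion: 106 scored components in total.
#' Respiratory and gastro-intestinal codes are sought in the 10 years before
#' the censoring date; the other three categories over the whole record.
#' Antibiotic prescriptions are counted over the 4 years before the censoring
#' date (enrollment-normalised when the patient is enrolled for less), and
#' prescriptions before the sixth birthday never count.
#'
#' @return A validated object of class `pad_ruleset`.
#' @seealso [load_ruleset()], [write_ruleset()], [component_count()]
#' @export
#' @examples
#' rs <- default_ruleset()
#' component_count(rs)                       # 106
#' subset(rs$antibiotics, atc_code == "J01CA04")$weight  # 2
default_ruleset <- function() {
  antibiotics <- tibble::tribble(
    ~atc_code, ~description, ~weight,
    "J01AA02", "Doxycycline", 2,
    "J01CA04", "Amoxicillin", 2,
    "J01CF05", "Flucloxacillin", 1,
    "J01CR02", "Amoxicillin/clavulanic acid", 2,
    "J01EE01", "Cotrimoxazole", 2,
    "J01FA01", "Erythromycin", 2,
    "J01FA09", "Clarithromycin", 2,
    "J01FA10", "Azithromycin", 2,
    "J01MA02", "Ciprofloxacin", 1,
    "J01MA12", "Levofloxacin", 2,
    "J01MA14", "Moxifloxacin", 2,
    "P01AB01", "Metronidazole", 1,
    "J01CE05", "Pheneticillin", 2,
    "J01CE02", "Phenoxymethylpenicillin", 2,
    "J01DB01", "Cefalexin", 2,
    "J01DC04", "Cefaclor", 2,
    "J01DD14", "Ceftibuten", 2,
    "J01DC02", "Cefuroxime axetil", 2,
    "S02CA03", "Hydrocortisone/colistin/bacitracin ear suspension", 0.5,
    "S02AA16", "Ofloxacin ear suspension", 0.5
  )

  rti <- icpc_rule_tbl(
    "respiratory_tract_infections",
    list("H01", "H04", "H71", "H72", "H74", "H74.01", "H74.02",
         "R05", "R07", "R09", "R73", "R74", "R74.01", "R96", "R90",
         "R72", "R72.01", "R72.02", "R74.02",
         "R75", "R75.01", "R75.02", "R76", "R76.01", "R76.02",
         "R77", "R77.01", "R77.02", "R78", "R81", "R91", "R91.01", "R91.02"),
    c("Ear pain", "Discharge from ear", "Acute otitis media/myringitis",
      "Otitis media with effusion", "Chronic otitis media/other ear infections",
      "Chronic otitis media", "Mastoiditis", "Coughing",
      "Sneezing/nasal congestion/running nose", "Symptoms/complaints sinuses",
      "Furuncle/abscess nose", "Acute upper respiratory tract infection",
      "Common cold", "Asthma", "Hypertrophy/chronic infection tonsils/adenoid",
      "Streptococcal pharyngitis/red spark", "Streptococcal pharyngitis",
      "Red spark", "Acute pharyngitis", "Acute/chronic rhinosinusitis",
      "Acute rhinosinusitis", "Chronic rhinosinusitis",
      "Acute tonsillitis/peritonsillar abscess", "Acute tonsillitis",
      "Peritonsillar abscess", "Acute laryngitis/tracheitis",
      "Subglottic laryngitis/pseudo croup", "Acute epiglottitis",
      "Acute bronchitis/bronchiolitis", "Pneumonia",
      "Chronic bronchitis/bronchiectasis", "Chronic bronchitis",
      "Bronchiectasis"),
    c(1, 1, 2, 2, 1, 1, 2, 1, 0.5, 1, 2, 2, 1, 2, 2,
      1, 1, 1, 1, 2, 2, 2, 2, 2, 1, 2, 1, 1, 2, 3, 1, 1, 4)
  )

  gi <- icpc_rule_tbl(
    "gastro_intestinal",
    list("D11", "D70", "D70.01", "D70.02", "D70.03", "D73", "D86", "D93",
         "D94", "D94.01"),
    c("Diarrhea", "Infectious diarrhea, dysentery", "Salmonella",
      "Shigella/Yersinia/Campylobacter intestinal infection", "Giardia",
      "Presumed gastro-intestinal infection", "Other peptic ulcer",
      "Inflammatory bowel syndrome", "Ulcerative colitis/chronic enteritis",
      "Ulcerative colitis"),
    c(2, 1, 1, 2, 2, 2, 1, 1, 1, 1)
  )

  other_inf <- icpc_rule_tbl(
    "other_infections",
    list("L70.01", "L70.02", "N71", "N71.01", "N71.02", "N71.03", "N71.04"),
    c("Osteomyelitis", "Septic arthritis", "Meningitis/encephalitis",
      "Bacterial meningitis", "Viral meningitis", "Encephalitis", "Myelitis"),
    c(1, 1, 2, 2, 2, 2, 2)
  )

  auto_immune <- icpc_rule_tbl(
    "auto_immune",
    list("B04", "B81", "B82", "B83", "B83.02", "L88", "L88.01", "R83.02",
         "S23.01", "S99.04", "T86", "T99.02", "T99.12", "D94.02", "D99.06",
         "N99"),
    c("Symptoms/complaints blood/blood forming organs",
      "Pernicious/folic acid anemia", "Other/non specified anemia",
      "Purpura/coagulation disorder/aberrant thrombocytes",
      "Idiopathic thrombocytopenic purpura (ITP)",
      "Rheumatoid arthritis/related diseases", "Rheumatoid arthritis",
      "Sarcoidosis", "Alopecia areata", "Vitiligo", "Hypothyroidism",
      "Thyroiditis", "Adrenal insufficiency", "Crohn's disease",
      "Coeliac disease", "Myasthenia gravis"),
    c(1, 1, 1, 1, 2, 1, 2, 1, 1, 1, 1, 1, 1, 2, 1, 1)
  )

  # B72 and B72.01 carry the same description and weight and are merged into
  # one component that fires on either code; B72.02 (non-Hodgkin) is separate.
  malignancy <- icpc_rule_tbl(
    "malignancy_lymphoproliferative_other",
    list("D74", c("B72", "B72.01"), "B72.02", "T08", "B87", "B02", "D96",
         "T10", "A04", "B84", "N94"),
    c("Gastric cancer", "Hodgkin's disease", "Non-Hodgkin lymphoma",
      "Weight loss", "Splenomegaly", "Lymphadenopathy", "Hepatomegaly",
      "Failure to thrive", "Fatigue/weakness", "Aberrant leukocytes",
      "Other peripheral neuritis/neuropathy"),
    c(1, 1, 2, 1, 2, 1, 1, 2, 1, 0.5, 1)
  )

  labs <- tibble::tribble(
    ~analyte, ~threshold, ~weight,
    "IgG_total", 7,    8,
    "IgG1",      4.9,  8,
    "IgG2",      1.5,  8,
    "IgG3",      0.2,  8,
    "IgG4",      0.08, 8,
    "IgM_total", 0.4,  8,
    "IgA_total", 0.7,  4,
    "calculated_globulin", 18, 6
  )

  ambiguous <- tibble::tribble(
    ~icpc_code, ~description,
    "B72",    "Hodgkin's lymphoma",
    "B72.01", "Hodgkin's lymphoma",
    "B72.02", "Non-Hodgkin lymphoma",
    "A87.02", "Post-transplantation",
    "D74",    "Gastric cancer",
    # Printed as a second D74 row ("Colon or rectal cancer"); recorded under
    # D75, the standard ICPC-1 code for colorectal malignancy.
    "D75",    "Colon or rectal cancer"
  )

  exclusions <- tibble::tribble(
    ~icpc_code, ~description,
    "B73",    "Leukemia",
    "B74.01", "Multiple myeloma",
    "B90",    "HIV-infection",
    "B90.01", "HIV seropositive without symptoms",
    "B90.02", "AIDS/AIDS-related complex",
    "P15.01", "Alcoholism",
    "P15.02", "Delirium tremens",
    "P15.03", "Wernicke-Korsakoff",
    "P19.03", "Addiction to hard drugs",
    "T06",    "Anorexia nervosa/bulimia",
    "T06.01", "Anorexia nervosa",
    "T06.02", "Bulimia",
    "T99.01", "Immunodeficiency",
    "T99.10", "Cystic fibrosis"
  )

  rs <- structure(list(
    antibiotics = antibiotics,
    icpc = dplyr::bind_rows(rti, gi, other_inf, auto_immune, malignancy),
    labs = labs,
    visits = list(cutoff = 6L, window_days = 365L, weight = 3),
    windows = list(
      respiratory_tract_infections = 10,
      gastro_intestinal = 10,
      other_infections = "lifetime",
      auto_immune = "lifetime",
      malignancy_lymphoproliferative_other = "lifetime"
    ),
    antibiotic_window_years = 4,
    antibiotic_min_age_years = 6,
    ambiguous = ambiguous,
    exclusions = exclusions,
    age_min = 12L,
    age_max = 70L
  ), class = "pad_ruleset")
  validate_ruleset(rs)
}

#' Validate a rule set
#'
#' Checks the structural invariants: positive weights and thresholds, one lab
#' rule per analyte, unique (codes, category) pairs, a window for every
#' category, disjoint ambiguous and exclusion code sets, visit cutoff >= 1,
#' and sane age bounds. Invisibly returns its argument so it can be chained.
#'
#' @param rs A `pad_ruleset`.
#' @return `rs`, invisibly, or an error describing the violated invariant.
#' @export
validate_ruleset <- function(rs) {
  if (!inherits(rs, "pad_ruleset")) abort("Not a pad_ruleset object")
  ab <- rs$antibiotics
  if (any(ab$weight <= 0)) abort("antibiotics: weight must be > 0")
  if (anyDuplicated(ab$atc_code)) abort("antibiotics: duplicate atc_code")
  normalize_atc(ab$atc_code, strict = TRUE)

  ic <- rs$icpc
  if (any(ic$weight <= 0)) abort("icpc: weight must be > 0")
  if (!all(ic$category %in% icpc_categories())) {
    abort(paste0("icpc: unknown category: ",
                 paste(setdiff(unique(ic$category), icpc_categories()), collapse = ", ")))
  }
  key <- paste(ic$component_id, ic$category)
  if (anyDuplicated(key)) abort("icpc: duplicate (codes, category) pair")
  for (cat in unique(ic$category)) {
    if (is.null(rs$windows[[cat]])) {
      abort(paste0("windows: no window entry for category ", cat))
    }
  }
  for (w in rs$windows) {
    ok <- identical(w, "lifetime") || (is.numeric(w) && length(w) == 1 && w > 0)
    if (!ok) abort("windows: each entry must be a positive number of years or \"lifetime\"")
  }

  lb <- rs$labs
  if (any(lb$threshold <= 0)) abort("labs: threshold must be > 0")
  if (any(lb$weight <= 0)) abort("labs: weight must be > 0")
  if (anyDuplicated(lb$analyte)) abort("labs: one rule per analyte")
  if (!all(lb$analyte %in% lab_analytes())) {
    abort(paste0("labs: unknown analyte: ",
                 paste(setdiff(lb$analyte, lab_analytes()), collapse = ", ")))
  }

  v <- rs$visits
  if (v$cutoff < 1) abort("visits: cutoff must be >= 1")
  if (v$weight <= 0) abort("visits: weight must be > 0")
  if (v$window_days < 1) abort("visits: window_days must be >= 1")

  overlap <- intersect(rs$ambiguous$icpc_code, rs$exclusions$icpc_code)
  if (length(overlap) > 0) {
    abort(paste0("ambiguous and exclusion code sets overlap: ",
                 paste(overlap, collapse = ", ")))
  }
  scored <- unlist(ic$codes)
  bad <- intersect(scored, rs$exclusions$icpc_code)
  if (length(bad) > 0) {
    abort(paste0("scored ICPC code(s) also listed as exclusions: ",
                 paste(bad, collapse = ", ")))
  }
  if (!(rs$age_min >= 0 && rs$age_max > rs$age_min)) {
    abort("age bounds: need 0 <= age_min < age_max")
  }
  if (rs$antibiotic_window_years <= 0 || rs$antibiotic_min_age_years < 0) {
    abort("antibiotic window/min-age must be positive")
  }
  invisible(rs)
}

#' Number of distinct scored components
#'
#' Antibiotic rules + diagnosis components (merged Hodgkin counted once) +
#' laboratory rules + the visit criterion.
#'
#' @param rs A `pad_ruleset`.
#' @return Integer count (106 for [default_ruleset()]).
#' @export
component_count <- function(rs) {
  validate_ruleset(rs)
  nrow(rs$antibiotics) + nrow(rs$icpc) + nrow(rs$labs) + 1L
}

#' Identifiers of every scored component
#'
#' @param rs A `pad_ruleset`.
#' @return Character vector, one id per component, in block order:
#'   `atc:<code>`, `icpc:<codes>`, `lab:<analyte>`, `visits`.
#' @export
component_ids <- function(rs) {
  c(paste0("atc:", rs$antibiotics$atc_code),
    paste0("icpc:", rs$icpc$component_id),
    paste0("lab:", rs$labs$analyte),
    "visits")
}

#' @export
print.pad_ruleset <- function(x, ...) {
  cat("<pad_ruleset>\n")
  cat("  antibiotic rules :", nrow(x$antibiotics), "\n")
  tab <- table(factor(x$icpc$category, levels = icpc_categories()))
  for (cat_name in names(tab)) {
    cat(sprintf("  icpc %-37s: %d\n", cat_name, tab[[cat_name]]))
  }
  cat("  lab rules        :", nrow(x$labs), "\n")
  cat("  visit criterion  : >=", x$visits$cutoff, "visits/",
      x$visits$window_days, "days ->", x$visits$weight, "points\n")
  cat("  ambiguous codes  :", nrow(x$ambiguous), "\n")
  cat("  exclusion codes  :", nrow(x$exclusions),
      sprintf("(+ age bounds %d-%d)\n", x$age_min, x$age_max))
  cat("  total components :", component_count(x), "\n")
  invisible(x)
}

ruleset_keys <- c("antibiotics", "icpc_categories", "labs", "visits",
                  "ambiguous", "exclusions", "age_bounds", "windows",
                  "antibiotic_window_years", "antibiotic_min_age_years")

#' Write a rule set to a YAML configuration file
#'
#' @param rs A `pad_ruleset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [load_ruleset()]
#' @export
write_ruleset <- function(rs, path) {
  validate_ruleset(rs)
  cats <- list()
  for (cat_name in icpc_categories()) {
    rows <- rs$icpc[rs$icpc$category == cat_name, ]
    cats[[cat_name]] <- purrr::pmap(
      list(rows$codes, rows$description, rows$weight),
      function(codes, description, weight) {
        list(codes = as.list(codes), description = description, weight = weight)
      }
    )
  }
  cfg <- list(
    antibiotics = purrr::pmap(rs$antibiotics, function(atc_code, description, weight) {
      list(atc_code = atc_code, description = description, weight = weight)
    }),
    icpc_categories = cats,
    labs = purrr::pmap(rs$labs, function(analyte, threshold, weight) {
      list(analyte = analyte, threshold = threshold, weight = weight)
    }),
    visits = rs$visits,
    ambiguous = purrr::pmap(rs$ambiguous, function(icpc_code, description) {
      list(icpc_code = icpc_code, description = description)
    }),
    exclusions = purrr::pmap(rs$exclusions, function(icpc_code, description) {
      list(icpc_code = icpc_code, description = description)
    }),
    age_bounds = list(min = rs$age_min, max = rs$age_max),
    windows = rs$windows,
    antibiotic_window_years = rs$antibiotic_window_years,
    antibiotic_min_age_years = rs$antibiotic_min_age_years
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Load a rule set from a YAML configuration file
#'
#' The file must follow the schema written by [write_ruleset()] (top-level
#' keys `antibiotics`, `icpc_categories`, `labs`, `visits`, `ambiguous`,
#' `exclusions`, `age_bounds`, `windows`, `antibiotic_window_years`,
#' `antibiotic_min_age_years`). Unknown top-level keys are rejected, as is
#' any configuration that fails [validate_ruleset()].
#'
#' @param path Path to the YAML file. Defaults to the configuration shipped
#'   with the package, which reproduces the published algorithm.
#' @return A validated `pad_ruleset`.
#' @export
load_ruleset <- function(path = system.file("extdata", "pad_ruleset.yaml",
                                            package = "padscreen")) {
  if (!file.exists(path)) abort(paste0("Rule-set file not found: ", path))
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), ruleset_keys)
  if (length(unknown) > 0) {
    abort(paste0("Unknown rule-set key(s): ", paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(ruleset_keys, names(cfg))
  if (length(missing) > 0) {
    abort(paste0("Missing rule-set key(s): ", paste(missing, collapse = ", ")))
  }
  need <- function(entry, fields, where) {
    miss <- setdiff(fields, names(entry))
    if (length(miss) > 0) {
      abort(paste0(where, ": entry missing field(s): ", paste(miss, collapse = ", ")))
    }
  }
  ab <- purrr::map_dfr(cfg$antibiotics, function(e) {
    need(e, c("atc_code", "description", "weight"), "antibiotics")
    tibble::tibble(atc_code = normalize_atc(e$atc_code),
                   description = e$description, weight = as.numeric(e$weight))
  })
  ic <- purrr::map_dfr(names(cfg$icpc_categories), function(cat_name) {
    purrr::map_dfr(cfg$icpc_categories[[cat_name]], function(e) {
      need(e, c("codes", "description", "weight"), paste0("icpc_categories/", cat_name))
      codes <- normalize_icpc(unlist(e$codes), strict = TRUE)
      tibble::tibble(component_id = paste(codes, collapse = "/"),
                     codes = list(codes), description = e$description,
                     weight = as.numeric(e$weight), category = cat_name)
    })
  })
  lb <- purrr::map_dfr(cfg$labs, function(e) {
    need(e, c("analyte", "threshold", "weight"), "labs")
    tibble::tibble(analyte = e$analyte, threshold = as.numeric(e$threshold),
                   weight = as.numeric(e$weight))
  })
  need(cfg$visits, c("cutoff", "window_days", "weight"), "visits")
  need(cfg$age_bounds, c("min", "max"), "age_bounds")
  amb <- purrr::map_dfr(cfg$ambiguous, function(e) {
    need(e, c("icpc_code", "description"), "ambiguous")
    tibble::tibble(icpc_code = normalize_icpc(e$icpc_code, strict = TRUE),
                   description = e$description)
  })
  exc <- purrr::map_dfr(cfg$exclusions, function(e) {
    need(e, c("icpc_code", "description"), "exclusions")
    tibble::tibble(icpc_code = normalize_icpc(e$icpc_code, strict = TRUE),
                   description = e$description)
  })
  rs <- structure(list(
    antibiotics = ab,
    icpc = ic,
    labs = lb,
    visits = list(cutoff = as.integer(cfg$visits$cutoff),
                  window_days = as.integer(cfg$visits$window_days),
                  weight = as.numeric(cfg$visits$weight)),
    windows = cfg$windows,
    antibiotic_window_years = as.numeric(cfg$antibiotic_window_years),
    antibiotic_min_age_years = as.numeric(cfg$antibiotic_min_age_years),
    ambiguous = amb,
    exclusions = exc,
    age_min = as.integer(cfg$age_bounds$min),
    age_max = as.integer(cfg$age_bounds$max)
  ), class = "pad_ruleset")
  validate_ruleset(rs)
}

#' Look-back window of an ICPC category, in days
#'
#' @param rs A `pad_ruleset`.
#' @param category One of [icpc_categories()].
#' @return Number of days (365 per year), or `Inf` for lifetime windows.
#' @export
category_window_days <- function(rs, category) {
  w <- rs$windows[[category]]
  if (is.null(w)) abort(paste0("Unknown category: ", category))
  if (identical(w, "lifetime")) Inf else as.numeric(w) * 365
}
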