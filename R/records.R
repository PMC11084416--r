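#' Drug exposure episode
#'
#' One administration episode of one drug for one patient: the exposure
#' window, the clinical course after withdrawal (dechallenge), any
#' re-exposure outcome (rechallenge), and the strength of the prior
#' literature association between the drug and DRESS (notoriety).
#'
#' @param drug_name Drug identifier (non-empty string).
#' @param start_date First administration (ISO-8601 date or `Date`).
#' @param stop_date Last administration; `NA` when the drug was not withdrawn.
#' @param notoriety One of `"well_known"`, `"occasionally_reported"`,
#'   `"unknown"`.
#' @param dechallenge One of `"improved_after_withdrawal"`, `"not_improved"`,
#'   `"not_withdrawn"`, `"unassessable"`.
#' @param rechallenge One of `"positive"`, `"negative"`, `"not_done"`.
#' @param is_culprit_truth Optional logical: simulation ground truth marking
#'   the exposure as the true culprit. `NA` for real-world records.
#' @return A `drug_exposure` object (named list).
#' @export
drug_exposure <- function(drug_name, start_date, stop_date = NA,
                          notoriety = "unknown",
                          dechallenge = "unassessable",
                          rechallenge = "not_done",
                          is_culprit_truth = NA) {
  if (length(drug_name) != 1L || is.na(drug_name) || !nzchar(drug_name)) {
    stop("drug_name must be a non-empty string", call. = FALSE)
  }
  start <- .as_date(start_date, "start_date", drug_name)
  stop_ <- .as_date_or_na(stop_date, "stop_date", drug_name)
  if (!is.na(stop_) && stop_ < start) {
    stop(sprintf("stop_date precedes start_date for drug '%s'", drug_name),
         call. = FALSE)
  }
  structure(list(
    drug_name = as.character(drug_name),
    start_date = start,
    stop_date = stop_,
    notoriety = .check_enum(notoriety, NOTORIETY_LEVELS, "notoriety", drug_name),
    dechallenge = .check_enum(dechallenge, DECHALLENGE_LEVELS, "dechallenge",
                              drug_name),
    rechallenge = .check_enum(rechallenge, RECHALLENGE_LEVELS, "rechallenge",
                              drug_name),
    is_culprit_truth = as.logical(is_culprit_truth)
  ), class = "drug_exposure")
}

#' Microbiology screening results
#'
#' Per-pathogen screening outcomes (herpesviruses, hepatitis viruses, HIV,
#' parvovirus, mycobacteria) used to score the "alternative infectious
#' cause" item. One record per pathogen; a pathogen that was never tested is
#' `not_recorded`.
#'
#' @param pathogen Character vector of pathogen names (subset of
#'   `HHV6, EBV, CMV, HSV, VZV, parvovirus, HCV, HBV, HIV, mycobacteria`).
#' @param method Matching vector of `"PCR"`, `"immunoassay"`, `"unspecified"`.
#' @param result Matching vector of `"positive"`, `"negative"`,
#'   `"not_recorded"`.
#' @return A data frame with one row per pathogen, all ten pathogens present.
#' @export
microbiology_results <- function(pathogen = character(),
                                 method = character(),
                                 result = character()) {
  stopifnot(length(pathogen) == length(method),
            length(pathogen) == length(result))
  if (anyDuplicated(pathogen)) {
    stop("one microbiology record per pathogen is allowed", call. = FALSE)
  }
  for (i in seq_along(pathogen)) {
    .check_enum(pathogen[i], PATHOGENS, "pathogen")
    .check_enum(method[i], MICRO_METHODS, "method", pathogen[i])
    .check_enum(result[i], MICRO_RESULTS, "result", pathogen[i])
  }
  full <- data.frame(pathogen = PATHOGENS,
                     method = "unspecified",
                     result = "not_recorded",
                     stringsAsFactors = FALSE)
  idx <- match(pathogen, full$pathogen)
  full$method[idx] <- method
  full$result[idx] <- result
  full
}

#' Immunology work-up
#'
#' Lymphocyte transformation test (LTT) and epicutaneous patch test outcomes.
#'
#' @param ltt,patch_test `"positive"`, `"negative"`, or `"not_done"`.
#' @return An `immunology_result` object.
#' @export
immunology_result <- function(ltt = "not_done", patch_test = "not_done") {
  structure(list(
    ltt = .check_enum(ltt, TEST_RESULTS, "ltt"),
    patch_test = .check_enum(patch_test, TEST_RESULTS, "patch_test")
  ), class = "immunology_result")
}

#' RegiSCAR diagnostic inputs
#'
#' The clinical criteria entering the RegiSCAR DRESS validation score:
#' fever, lymphadenopathy, eosinophilia, atypical lymphocytes, skin
#' involvement, biopsy, internal organ involvement, resolution time, and
#' exclusion of alternative causes.
#'
#' @param fever_ge_38_5,lymphadenopathy,atypical_lymphocytes,skin_extent_gt50,rash_suggestive,resolution_ge_15_days,alternative_causes_excluded
#'   `"yes"`, `"no"`, or `"unknown"`.
#' @param eosinophilia_grade `"none"`, `"moderate"`, `"marked"`, `"unknown"`.
#' @param biopsy_suggestive `"yes"`, `"no"`, `"not_done"`.
#' @param organs_involved Integer count of internal organs involved, 0-10.
#' @return A `regiscar_inputs` object.
#' @export
regiscar_inputs <- function(fever_ge_38_5 = "unknown",
                            lymphadenopathy = "unknown",
                            eosinophilia_grade = "unknown",
                            atypical_lymphocytes = "unknown",
                            skin_extent_gt50 = "unknown",
                            rash_suggestive = "unknown",
                            biopsy_suggestive = "not_done",
                            organs_involved = 0L,
                            resolution_ge_15_days = "unknown",
                            alternative_causes_excluded = "unknown") {
  organs <- suppressWarnings(as.integer(organs_involved))
  if (length(organs) != 1L || is.na(organs) || organs < 0L || organs > 10L) {
    stop("organs_involved must be an integer in [0, 10]", call. = FALSE)
  }
  structure(list(
    fever_ge_38_5 = .check_enum(fever_ge_38_5, YNU_LEVELS, "fever_ge_38_5"),
    lymphadenopathy = .check_enum(lymphadenopathy, YNU_LEVELS,
                                  "lymphadenopathy"),
    eosinophilia_grade = .check_enum(eosinophilia_grade, EOSINOPHILIA_LEVELS,
                                     "eosinophilia_grade"),
    atypical_lymphocytes = .check_enum(atypical_lymphocytes, YNU_LEVELS,
                                       "atypical_lymphocytes"),
    skin_extent_gt50 = .check_enum(skin_extent_gt50, YNU_LEVELS,
                                   "skin_extent_gt50"),
    rash_suggestive = .check_enum(rash_suggestive, YNU_LEVELS,
                                  "rash_suggestive"),
    biopsy_suggestive = .check_enum(biopsy_suggestive, BIOPSY_LEVELS,
                                    "biopsy_suggestive"),
    organs_involved = organs,
    resolution_ge_15_days = .check_enum(resolution_ge_15_days, YNU_LEVELS,
                                        "resolution_ge_15_days"),
    alternative_causes_excluded = .check_enum(alternative_causes_excluded,
                                              YNU_LEVELS,
                                              "alternative_causes_excluded")
  ), class = "regiscar_inputs")
}

#' Patient record
#'
#' One subject of a DRESS causality study: demographics, reaction onset and
#' resolution dates, RegiSCAR criteria, one or more drug exposures,
#' microbiology and immunology work-up, and the case/control label. Cases
#' are patients in whom the culprit drug was the only drug administered
#' (exactly one exposure); controls had several suspect drugs (two or more
#' exposures).
#'
#' @param patient_id Opaque non-empty identifier.
#' @param age Age in years (non-negative).
#' @param sex `"male"` or `"female"`.
#' @param index_date Reaction onset date.
#' @param exposures List of [drug_exposure()] objects (at least one).
#' @param regiscar A [regiscar_inputs()] object.
#' @param autoimmune_history One of `"none_or_unknown"`,
#'   `"rheumatoid_arthritis"`, `"psoriatic_arthritis"`,
#'   `"ankylosing_spondylitis"`, `"other"`.
#' @param resolution_date Optional resolution date (must not precede
#'   `index_date`).
#' @param microbiology Data frame from [microbiology_results()].
#' @param immunology An [immunology_result()] object.
#' @param group `"case"`, `"control"`, or `"unlabeled"`.
#' @return A validated `patient_record` object.
#' @export
patient_record <- function(patient_id, age, sex, index_date, exposures,
                           regiscar = regiscar_inputs(),
                           autoimmune_history = "none_or_unknown",
                           resolution_date = NA,
                           microbiology = microbiology_results(),
                           immunology = immunology_result(),
                           group = "unlabeled") {
  if (length(patient_id) != 1L || is.na(patient_id) || !nzchar(patient_id)) {
    stop("patient_id must be a non-empty string", call. = FALSE)
  }
  rec <- structure(list(
    patient_id = as.character(patient_id),
    age = as.numeric(age),
    sex = .check_enum(sex, SEX_LEVELS, "sex", patient_id),
    autoimmune_history = .check_enum(autoimmune_history, AUTOIMMUNE_LEVELS,
                                     "autoimmune_history", patient_id),
    index_date = .as_date(index_date, "index_date", patient_id),
    resolution_date = .as_date_or_na(resolution_date, "resolution_date",
                                     patient_id),
    regiscar = regiscar,
    exposures = exposures,
    microbiology = microbiology,
    immunology = immunology,
    group = .check_enum(group, GROUP_LEVELS, "group", patient_id)
  ), class = "patient_record")
  validate_patient_record(rec)
}

#' Validate a patient record
#'
#' Checks all domain invariants: date ordering, enum membership, and the
#' case/control exposure-count rules (a case has exactly one exposure, a
#' control at least two).
#'
#' @param rec A `patient_record`.
#' @return The record, invisibly usable; errors name the offending field.
#' @export
validate_patient_record <- function(rec) {
  id <- rec$patient_id
  if (is.na(rec$age) || rec$age < 0) {
    stop(sprintf("age must be a non-negative number for patient '%s'", id),
         call. = FALSE)
  }
  if (!inherits(rec$regiscar, "regiscar_inputs")) {
    stop(sprintf("regiscar inputs missing for patient '%s'", id),
         call. = FALSE)
  }
  if (!inherits(rec$immunology, "immunology_result")) {
    stop(sprintf("immunology result missing for patient '%s'", id),
         call. = FALSE)
  }
  if (!is.na(rec$resolution_date) && rec$resolution_date < rec$index_date) {
    stop(sprintf("resolution_date precedes index_date for patient '%s'", id),
         call. = FALSE)
  }
  if (!is.list(rec$exposures) || length(rec$exposures) < 1L) {
    stop(sprintf("patient '%s' must have at least one drug exposure", id),
         call. = FALSE)
  }
  for (e in rec$exposures) {
    if (!inherits(e, "drug_exposure")) {
      stop(sprintf("exposures of patient '%s' must be drug_exposure objects",
                   id), call. = FALSE)
    }
  }
  n_exp <- length(rec$exposures)
  if (rec$group == "case" && n_exp != 1L) {
    stop(sprintf(
      "patient '%s' is a case but has %d exposures (cases received a single drug)",
      id, n_exp), call. = FALSE)
  }
  if (rec$group == "control" && n_exp < 2L) {
    stop(sprintf(
      "patient '%s' is a control but has %d exposure (controls received several drugs)",
      id, n_exp), call. = FALSE)
  }
  invisible(rec)
}

#' Validate a cohort
#'
#' @param records List of `patient_record` objects.
#' @return The cohort, invisibly; errors name patient and field.
#' @export
validate_cohort <- function(records) {
  ids <- vapply(records, function(r) r$patient_id, character(1))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicated patient_id: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  for (r in records) validate_patient_record(r)
  invisible(records)
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record %s> %s, %.0f y, %s; onset %s; %d exposure(s): %s\n",
              x$patient_id, x$sex, x$age, x$group,
              format(x$index_date),
              length(x$exposures),
              paste(vapply(x$exposures, function(e) e$drug_name, character(1)),
                    collapse = ", ")))
  invisible(x)
}
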