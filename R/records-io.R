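# Cohort interchange. Two dialects:
#   csv  - one row per patient-drug pair; patient-level columns are repeated
#          and must be identical across a patient's rows (mismatch is an
#          error, never a silent overwrite).
#   json - one array of nested patient objects.
# Both round-trip through read_cohort()/write_cohort() with full fidelity.

.PATIENT_COLS <- c("patient_id", "age", "sex", "autoimmune_history",
                   "index_date", "resolution_date", "group",
                   "fever_ge_38_5", "lymphadenopathy", "eosinophilia_grade",
                   "atypical_lymphocytes", "skin_extent_gt50",
                   "rash_suggestive", "biopsy_suggestive", "organs_involved",
                   "resolution_ge_15_days", "alternative_causes_excluded",
                   "ltt", "patch_test")

.micro_cols <- function() {
  as.vector(rbind(paste0("micro_", tolower(PATHOGENS)),
                  paste0("micro_", tolower(PATHOGENS), "_method")))
}

.DRUG_COLS <- c("drug_name", "start_date", "stop_date", "notoriety",
                "dechallenge", "rechallenge", "is_culprit_truth")

.fmt_date <- function(d) ifelse(is.na(d), "", format(d, "%Y-%m-%d"))

.fmt_logical <- function(x) ifelse(is.na(x), "", ifelse(x, "true", "false"))

.parse_logical <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "1", "yes")] <- TRUE
  out[x %in% c("false", "0", "no")] <- FALSE
  out
}

#' Write a cohort to CSV or JSON
#'
#' @param records List of `patient_record` objects (may be empty).
#' @param path Output file path.
#' @param format `"csv"` (one row per patient-drug pair) or `"json"`
#'   (nested per-patient array).
#' @return `path`, invisibly.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  validate_cohort(records)
  if (format == "csv") {
    df <- cohort_to_table(records)
    utils::write.csv(df, path, row.names = FALSE, na = "")
  } else {
    out <- lapply(records, .record_to_list)
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                         null = "null", na = "null")
  }
  invisible(path)
}

#' Read a cohort from CSV or JSON
#'
#' In tabular form, per-drug rows sharing a `patient_id` are merged into one
#' [patient_record()]; repeated patient-level columns must agree exactly
#' across a patient's rows. Merging is order-insensitive.
#'
#' @param path Input file path.
#' @param format `"csv"` or `"json"`.
#' @return List of validated `patient_record` objects, in order of first
#'   appearance.
#' @export
read_cohort <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    recs <- lapply(raw, .record_from_list)
    return(validate_cohort(recs))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = NULL)
  expected <- c(.PATIENT_COLS, .micro_cols(), .DRUG_COLS)
  missing <- setdiff(expected, names(df))
  if (length(missing)) {
    stop(sprintf("cohort CSV is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0L) return(list())
  recs <- lapply(split(seq_len(nrow(df)), factor(df$patient_id,
                                                 levels = unique(df$patient_id))),
                 function(rows) .record_from_rows(df[rows, , drop = FALSE]))
  validate_cohort(unname(recs))
}

#' Flatten a cohort to the tabular (one row per patient-drug) form
#'
#' @param records List of `patient_record` objects.
#' @return A data frame in the documented CSV dialect.
#' @export
cohort_to_table <- function(records) {
  cols <- c(.PATIENT_COLS, .micro_cols(), .DRUG_COLS)
  if (length(records) == 0L) {
    df <- as.data.frame(matrix(character(0), nrow = 0, ncol = length(cols)),
                        stringsAsFactors = FALSE)
    names(df) <- cols
    return(df)
  }
  rows <- do.call(rbind, lapply(records, function(rec) {
    pat <- c(patient_id = rec$patient_id,
             age = format(rec$age, digits = 10),
             sex = rec$sex,
             autoimmune_history = rec$autoimmune_history,
             index_date = .fmt_date(rec$index_date),
             resolution_date = .fmt_date(rec$resolution_date),
             group = rec$group,
             unlist(rec$regiscar[c("fever_ge_38_5", "lymphadenopathy",
                                   "eosinophilia_grade", "atypical_lymphocytes",
                                   "skin_extent_gt50", "rash_suggestive",
                                   "biopsy_suggestive")]),
             organs_involved = as.character(rec$regiscar$organs_involved),
             resolution_ge_15_days = rec$regiscar$resolution_ge_15_days,
             alternative_causes_excluded = rec$regiscar$alternative_causes_excluded,
             ltt = rec$immunology$ltt,
             patch_test = rec$immunology$patch_test)
    mic <- rec$microbiology[match(PATHOGENS, rec$microbiology$pathogen), ]
    micv <- as.vector(rbind(mic$result, mic$method))
    names(micv) <- .micro_cols()
    do.call(rbind, lapply(rec$exposures, function(e) {
      c(pat, micv,
        drug_name = e$drug_name,
        start_date = .fmt_date(e$start_date),
        stop_date = .fmt_date(e$stop_date),
        notoriety = e$notoriety,
        dechallenge = e$dechallenge,
        rechallenge = e$rechallenge,
        is_culprit_truth = .fmt_logical(e$is_culprit_truth))
    }))
  }))
  df <- as.data.frame(rows, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df[, cols]
}

.record_from_rows <- function(rows) {
  id <- rows$patient_id[1]
  for (col in c(.PATIENT_COLS, .micro_cols())) {
    if (length(unique(rows[[col]])) != 1L) {
      stop(sprintf(
        "patient-level column '%s' differs across rows of patient '%s'",
        col, id), call. = FALSE)
    }
  }
  r1 <- rows[1, ]
  mic_res <- vapply(tolower(PATHOGENS),
                    function(p) r1[[paste0("micro_", p)]], character(1))
  mic_met <- vapply(tolower(PATHOGENS),
                    function(p) r1[[paste0("micro_", p, "_method")]],
                    character(1))
  keep <- mic_res != "not_recorded" | mic_met != "unspecified"
  exposures <- lapply(seq_len(nrow(rows)), function(i) {
    drug_exposure(rows$drug_name[i],
                  start_date = rows$start_date[i],
                  stop_date = rows$stop_date[i],
                  notoriety = rows$notoriety[i],
                  dechallenge = rows$dechallenge[i],
                  rechallenge = rows$rechallenge[i],
                  is_culprit_truth = .parse_logical(rows$is_culprit_truth[i]))
  })
  patient_record(
    patient_id = id,
    age = suppressWarnings(as.numeric(r1$age)),
    sex = r1$sex,
    autoimmune_history = r1$autoimmune_history,
    index_date = r1$index_date,
    resolution_date = r1$resolution_date,
    group = r1$group,
    regiscar = regiscar_inputs(
      fever_ge_38_5 = r1$fever_ge_38_5,
      lymphadenopathy = r1$lymphadenopathy,
      eosinophilia_grade = r1$eosinophilia_grade,
      atypical_lymphocytes = r1$atypical_lymphocytes,
      skin_extent_gt50 = r1$skin_extent_gt50,
      rash_suggestive = r1$rash_suggestive,
      biopsy_suggestive = r1$biopsy_suggestive,
      organs_involved = r1$organs_involved,
      resolution_ge_15_days = r1$resolution_ge_15_days,
      alternative_causes_excluded = r1$alternative_causes_excluded),
    microbiology = microbiology_results(PATHOGENS[keep], mic_met[keep],
                                        mic_res[keep]),
    immunology = immunology_result(ltt = r1$ltt, patch_test = r1$patch_test),
    exposures = exposures)
}

.record_to_list <- function(rec) {
  list(
    patient_id = rec$patient_id,
    age = rec$age,
    sex = rec$sex,
    autoimmune_history = rec$autoimmune_history,
    index_date = .fmt_date(rec$index_date),
    resolution_date = if (is.na(rec$resolution_date)) NULL else
      .fmt_date(rec$resolution_date),
    group = rec$group,
    regiscar = unclass(rec$regiscar),
    microbiology = lapply(seq_len(nrow(rec$microbiology)), function(i)
      as.list(rec$microbiology[i, ])),
    immunology = unclass(rec$immunology),
    exposures = lapply(rec$exposures, function(e) list(
      drug_name = e$drug_name,
      start_date = .fmt_date(e$start_date),
      stop_date = if (is.na(e$stop_date)) NULL else .fmt_date(e$stop_date),
      notoriety = e$notoriety,
      dechallenge = e$dechallenge,
      rechallenge = e$rechallenge,
      is_culprit_truth = if (is.na(e$is_culprit_truth)) NULL else
        e$is_culprit_truth))
  )
}

.record_from_list <- function(x) {
  mic <- x$microbiology %||% list()
  pathogen <- vapply(mic, function(m) m$pathogen, character(1))
  method <- vapply(mic, function(m) m$method %||% "unspecified", character(1))
  result <- vapply(mic, function(m) m$result %||% "not_recorded", character(1))
  keep <- result != "not_recorded" | method != "unspecified"
  rg <- x$regiscar %||% list()
  im <- x$immunology %||% list()
  patient_record(
    patient_id = x$patient_id,
    age = x$age,
    sex = x$sex,
    autoimmune_history = x$autoimmune_history %||% "none_or_unknown",
    index_date = x$index_date,
    resolution_date = x$resolution_date %||% NA,
    group = x$group %||% "unlabeled",
    regiscar = do.call(regiscar_inputs, rg),
    microbiology = microbiology_results(pathogen[keep], method[keep],
                                        result[keep]),
    immunology = immunology_result(ltt = im$ltt %||% "not_done",
                                   patch_test = im$patch_test %||% "not_done"),
    exposures = lapply(x$exposures, function(e) drug_exposure(
      drug_name = e$drug_name,
      start_date = e$start_date,
      stop_date = e$stop_date %||% NA,
      notoriety = e$notoriety %||% "unknown",
      dechallenge = e$dechallenge %||% "unassessable",
      rechallenge = e$rechallenge %||% "not_done",
      is_culprit_truth = e$is_culprit_truth %||% NA)))
}
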