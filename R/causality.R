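# Per-drug causality assessment. The engine itself is table-agnostic
# (.score_items + classify); what differs between ALDRESS and SEFV is the
# score table and the deriver that turns a patient record into item levels.

.NOTORIETY_RANK <- c(unknown = 1L, occasionally_reported = 2L, well_known = 3L)

# Microbiology-based alternative-cause level: any positive pathogen
# implicates an infectious alternative; a screen with at least one negative
# and no positives supports the drug; no recorded tests are neutral.
.micro_level <- function(microbiology) {
  res <- microbiology$result
  if (any(res == "positive")) "positive"
  else if (any(res == "negative")) "screens_negative"
  else "not_recorded"
}

# Combined LTT/patch immunology level; a positive LTT dominates (+3 cap).
.immuno_level <- function(immunology) {
  if (immunology$ltt == "positive") "ltt_positive"
  else if (immunology$patch_test == "positive") "patch_positive"
  else if (immunology$ltt == "negative" ||
           immunology$patch_test == "negative") "negative"
  else "not_done"
}

.derive_levels_aldress <- function(patient, exposure) {
  others <- Filter(function(e) !identical(e, exposure), patient$exposures)
  rank <- .NOTORIETY_RANK[[exposure$notoriety]]
  concomitant <- any(vapply(others, function(e)
    .NOTORIETY_RANK[[e$notoriety]] >= rank, logical(1)))
  list(
    chronology = assess_chronology_aldress(exposure,
                                           patient$index_date)$compatibility,
    dechallenge = exposure$dechallenge,
    rechallenge = exposure$rechallenge,
    notoriety = exposure$notoriety,
    alternative_cause = .micro_level(patient$microbiology),
    immunology = .immuno_level(patient$immunology),
    concomitant = if (concomitant) "present" else "none"
  )
}

.derive_levels_sefv <- function(patient, exposure) {
  supportive <- patient$immunology$ltt == "positive" ||
    patient$immunology$patch_test == "positive"
  list(
    chronology = assess_chronology_sefv(exposure,
                                        patient$index_date)$compatibility,
    literature = exposure$notoriety,
    withdrawal = exposure$dechallenge,
    rechallenge = exposure$rechallenge,
    alternative_causes = .micro_level(patient$microbiology),
    contributing_factors = if (patient$autoimmune_history !=
                               "none_or_unknown") "present" else "none",
    complementary_explorations = if (supportive) "supportive" else "none"
  )
}

.derive_levels <- function(patient, exposure, table) {
  switch(table$algorithm,
         aldress = .derive_levels_aldress(patient, exposure),
         sefv = .derive_levels_sefv(patient, exposure),
         stop(sprintf(
           "no item deriver for algorithm '%s'; score custom tables via classify()",
           table$algorithm), call. = FALSE))
}

#' Score one drug exposure for one patient
#'
#' Derives the item levels (chronology, dechallenge, rechallenge,
#' notoriety/literature, alternative infectious cause, immunology or
#' complementary explorations, concomitant-suspect or contributing
#' factors) from the record, sums the table's points, and classifies the
#' net score. For the ALDRESS algorithm the patient must first pass the
#' RegiSCAR inclusion gate (total > +2); a patient failing the gate is a
#' precondition error naming the offending score.
#'
#' @param patient A [patient_record()].
#' @param exposure One of the patient's [drug_exposure()] objects.
#' @param table A `score_table` (see [default_score_table()]).
#' @param regiscar_table Table used for the inclusion gate when scoring
#'   ALDRESS.
#' @return A `causality_assessment` list: `patient_id`, `drug_name`,
#'   `per_item_points`, `net_score`, `category`, `related`.
#' @export
score_drug <- function(patient, exposure,
                       table = default_score_table("aldress"),
                       regiscar_table = default_score_table("regiscar")) {
  stopifnot(inherits(patient, "patient_record"),
            inherits(exposure, "drug_exposure"),
            inherits(table, "score_table"))
  if (table$algorithm == "aldress") {
    rs <- regiscar_score(patient$regiscar, regiscar_table)
    if (!meets_inclusion(rs)) {
      stop(sprintf(
        "patient '%s' fails the RegiSCAR inclusion gate: score %+d is not greater than +2",
        patient$patient_id, rs$total_score), call. = FALSE)
    }
  }
  pts <- .score_items(.derive_levels(patient, exposure, table), table)
  net <- as.integer(sum(pts))
  cls <- classify(net, table)
  structure(list(
    patient_id = patient$patient_id,
    drug_name = exposure$drug_name,
    algorithm = table$algorithm,
    per_item_points = pts,
    net_score = net,
    category = cls$category,
    related = cls$related
  ), class = "causality_assessment")
}

#' @export
print.causality_assessment <- function(x, ...) {
  cat(sprintf("<%s assessment> %s / %s: net %+d (%s, %s)\n",
              x$algorithm, x$patient_id, x$drug_name, x$net_score,
              x$category, if (x$related) "related" else "unrelated"))
  invisible(x)
}

#' Assess every drug of every patient in a cohort
#'
#' Produces one assessment per (patient, drug) pair, in input order. When a
#' patient has several exposure episodes of the same drug, the episode with
#' the most compatible chronology is scored. Patients failing the RegiSCAR
#' gate (ALDRESS only) either abort the run (`on_gate_failure = "error"`)
#' or are skipped with a warning, which lets mixed real-world cohorts be
#' processed in one pass.
#'
#' @param records List of `patient_record` objects.
#' @param table A `score_table`.
#' @param on_gate_failure `"error"` or `"skip"`.
#' @param regiscar_table Table for the inclusion gate.
#' @return A data frame with columns `patient_id`, `drug_name`, one column
#'   of points per item, `net_score`, `category`, `related`; attribute
#'   `algorithm`.
#' @export
assess_cohort <- function(records, table = default_score_table("aldress"),
                          on_gate_failure = c("error", "skip"),
                          regiscar_table = default_score_table("regiscar")) {
  on_gate_failure <- match.arg(on_gate_failure)
  validate_cohort(records)
  compat_rank <- c(compatible = 1L, partially_compatible = 2L,
                   incompatible = 3L, excluding = 4L)
  chron_fn <- if (table$algorithm == "sefv") assess_chronology_sefv
              else assess_chronology_aldress
  rows <- list()
  skipped <- character()
  for (rec in records) {
    if (table$algorithm == "aldress") {
      rs <- regiscar_score(rec$regiscar, regiscar_table)
      if (!meets_inclusion(rs)) {
        if (on_gate_failure == "error") {
          stop(sprintf(
            "patient '%s' fails the RegiSCAR inclusion gate: score %+d is not greater than +2",
            rec$patient_id, rs$total_score), call. = FALSE)
        }
        skipped <- c(skipped, sprintf("%s (RegiSCAR %+d)", rec$patient_id,
                                      rs$total_score))
        next
      }
    }
    drugs <- vapply(rec$exposures, function(e) e$drug_name, character(1))
    for (d in unique(drugs)) {
      episodes <- rec$exposures[drugs == d]
      if (length(episodes) > 1L) {
        r <- vapply(episodes, function(e)
          compat_rank[[chron_fn(e, rec$index_date)$compatibility]], integer(1))
        episodes <- episodes[order(r)]
      }
      rows[[length(rows) + 1L]] <- score_drug(rec, episodes[[1L]], table,
                                              regiscar_table)
    }
  }
  if (length(skipped)) {
    warning(sprintf("skipped %d patient(s) failing the RegiSCAR gate: %s",
                    length(skipped), paste(skipped, collapse = "; ")),
            call. = FALSE)
  }
  assessments_to_table(rows, table)
}

#' Tabulate a list of causality assessments
#'
#' @param assessments List of `causality_assessment` objects.
#' @param table The score table they were produced with (fixes the item
#'   column order).
#' @return Data frame mirroring the per-drug assessment layout.
#' @export
assessments_to_table <- function(assessments, table) {
  item_ids <- vapply(table$items, function(it) it$id, character(1))
  if (length(assessments) == 0L) {
    df <- data.frame(patient_id = character(), drug_name = character(),
                     stringsAsFactors = FALSE)
    for (id in item_ids) df[[id]] <- integer()
    df$net_score <- integer(); df$category <- character()
    df$related <- logical()
    attr(df, "algorithm") <- table$algorithm
    return(df)
  }
  df <- data.frame(
    patient_id = vapply(assessments, `[[`, character(1), "patient_id"),
    drug_name = vapply(assessments, `[[`, character(1), "drug_name"),
    stringsAsFactors = FALSE)
  for (id in item_ids) {
    df[[id]] <- vapply(assessments, function(a) a$per_item_points[[id]],
                       integer(1))
  }
  df$net_score <- vapply(assessments, `[[`, integer(1), "net_score")
  df$category <- vapply(assessments, `[[`, character(1), "category")
  df$related <- vapply(assessments, `[[`, logical(1), "related")
  attr(df, "algorithm") <- table$algorithm
  df
}
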