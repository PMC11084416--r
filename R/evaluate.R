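# Patient-level evaluation of a causality algorithm against the
# case-control reference. The unit of analysis is the patient:
#   - a case (single-drug patient) is predicted positive when its only
#     drug is called related — a miss is a false negative;
#   - a control (multi-drug patient) is predicted positive when the
#     algorithm wrongly implicates an innocent concomitant, i.e. calls any
#     non-culprit drug related — a false accusation is the false positive.
# Correctly flagging a control's true culprit is correct behaviour, not a
# false alarm, so controls require per-drug ground-truth labels.

#' Patient-level binary calls for evaluation
#'
#' @param records List of `patient_record` objects with group labels
#'   (`case`/`control`) and, for controls, `is_culprit_truth` flags on
#'   every exposure.
#' @param assessments Data frame from [assess_cohort()] run on `records`.
#' @return Data frame with one row per patient: `patient_id`, `truth`
#'   (case = `TRUE`), `predicted`.
#' @export
patient_calls <- function(records, assessments) {
  validate_cohort(records)
  rows <- lapply(records, function(rec) {
    if (!rec$group %in% c("case", "control")) {
      stop(sprintf("patient '%s' has no case/control label; evaluation %s",
                   rec$patient_id, "requires labeled records"),
           call. = FALSE)
    }
    a <- assessments[assessments$patient_id == rec$patient_id, , drop = FALSE]
    if (nrow(a) == 0L) {
      stop(sprintf("no assessments found for patient '%s'", rec$patient_id),
           call. = FALSE)
    }
    predicted <- if (rec$group == "case") {
      any(a$related)
    } else {
      truth_flags <- vapply(rec$exposures, function(e) e$is_culprit_truth,
                            logical(1))
      if (anyNA(truth_flags)) {
        stop(sprintf(
          "control '%s' lacks is_culprit_truth labels on its exposures",
          rec$patient_id), call. = FALSE)
      }
      innocents <- vapply(rec$exposures[!truth_flags],
                          function(e) e$drug_name, character(1))
      any(a$related[a$drug_name %in% innocents])
    }
    data.frame(patient_id = rec$patient_id,
               truth = rec$group == "case",
               predicted = predicted, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evaluate a causality algorithm on a labeled cohort
#'
#' Scores every drug of every patient, reduces to patient-level calls (see
#' [patient_calls()]), and reports the 2x2 diagnostic-accuracy suite with
#' exact confidence intervals plus Fisher's exact test of the
#' call-label association.
#'
#' @param records Labeled cohort.
#' @param table Score table of the algorithm under evaluation.
#' @param alpha Significance level for the intervals.
#' @param regiscar_table Table for the ALDRESS inclusion gate.
#' @return An `algorithm_evaluation` list: `assessments`, `calls`,
#'   `confusion`, `report` ([diagnostic_report()]), `fisher_p`.
#' @examples
#' sim <- generate_cohort(cohort_profile(), seed = 42)
#' ev <- evaluate_algorithm(sim$records, default_score_table("aldress"))
#' ev$report
#' @export
evaluate_algorithm <- function(records,
                               table = default_score_table("aldress"),
                               alpha = 0.05,
                               regiscar_table = default_score_table("regiscar")) {
  assessments <- assess_cohort(records, table,
                               regiscar_table = regiscar_table)
  calls <- patient_calls(records, assessments)
  cm <- confusion(calls$truth, calls$predicted)
  structure(list(
    algorithm = table$algorithm,
    assessments = assessments,
    calls = calls,
    confusion = cm,
    report = diagnostic_report(cm, alpha),
    fisher_p = fisher_exact(cm)
  ), class = "algorithm_evaluation")
}

#' @export
print.algorithm_evaluation <- function(x, ...) {
  cat(sprintf("Evaluation of algorithm '%s' on %d patients\n",
              x$algorithm, nrow(x$calls)))
  print(x$confusion)
  print(x$report)
  cat(sprintf("  %-28s %.4g\n", "Fisher exact p", x$fisher_p))
  invisible(x)
}
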