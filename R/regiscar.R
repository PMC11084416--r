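#' RegiSCAR DRESS validation score
#'
#' Computes the itemized RegiSCAR score from the clinical criteria and maps
#' the total to its diagnostic category: total of +1 or less is
#' `excluded`, +2 to +3 `possible`, +4 `probable`, +5 or more `definite`.
#'
#' @param inputs A [regiscar_inputs()] object.
#' @param table Score table; defaults to the shipped RegiSCAR table.
#' @return A `regiscar_result` list with `total_score`, `per_item_points`,
#'   and `category`.
#' @examples
#' ri <- regiscar_inputs(fever_ge_38_5 = "yes", eosinophilia_grade = "marked",
#'                       rash_suggestive = "yes", organs_involved = 2,
#'                       resolution_ge_15_days = "yes",
#'                       alternative_causes_excluded = "yes")
#' regiscar_score(ri)
#' @export
regiscar_score <- function(inputs, table = default_score_table("regiscar")) {
  stopifnot(inherits(inputs, "regiscar_inputs"), inherits(table, "score_table"))
  levels <- list(
    fever_ge_38_5 = inputs$fever_ge_38_5,
    lymphadenopathy = inputs$lymphadenopathy,
    eosinophilia = inputs$eosinophilia_grade,
    atypical_lymphocytes = inputs$atypical_lymphocytes,
    skin_extent_gt50 = inputs$skin_extent_gt50,
    rash_suggestive = inputs$rash_suggestive,
    biopsy_suggestive = inputs$biopsy_suggestive,
    organ_involvement = if (inputs$organs_involved >= 2L) "two_or_more"
                        else if (inputs$organs_involved == 1L) "one"
                        else "none",
    resolution_ge_15_days = inputs$resolution_ge_15_days,
    alternative_causes_excluded = inputs$alternative_causes_excluded
  )
  pts <- .score_items(levels, table)
  total <- sum(pts)
  structure(list(
    total_score = as.integer(total),
    per_item_points = pts,
    category = classify(total, table)$category
  ), class = "regiscar_result")
}

#' RegiSCAR inclusion gate for causality assessment
#'
#' DRESS causality is only assessed in patients whose RegiSCAR total is
#' strictly greater than +2 (i.e. at least a possible DRESS with score
#' +3 or higher).
#'
#' @param result A `regiscar_result` from [regiscar_score()].
#' @return `TRUE` iff `total_score > 2`.
#' @export
meets_inclusion <- function(result) {
  stopifnot(inherits(result, "regiscar_result"))
  result$total_score > 2L
}

#' @export
print.regiscar_result <- function(x, ...) {
  cat(sprintf("<regiscar_result> total %+d (%s)\n", x$total_score, x$category))
  invisible(x)
}
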