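# Chronology windows. Latency is index_date - start_date in whole days
# (day 0 = started the day of onset). A drug started on or after the onset
# date can never have caused the reaction: compatibility "excluding".

.chronology_finding <- function(exposure, index_date, compat_fn) {
  latency <- as.integer(index_date - exposure$start_date)
  overlap <- if (latency <= 0L) {
    "onset_before_start"
  } else if (!is.na(exposure$stop_date) && index_date > exposure$stop_date) {
    "onset_after_stop"
  } else {
    "onset_during_exposure"
  }
  compatibility <- if (latency <= 0L) "excluding" else compat_fn(latency)
  structure(list(latency_days = latency, overlap = overlap,
                 compatibility = compatibility),
            class = "chronology_finding")
}

#' SEFV chronology assessment
#'
#' General adverse-reaction latency windows: onset 1-7 days after the drug
#' start is compatible, 8-21 days partially compatible (rare late
#' presentations), beyond 21 days incompatible, and a drug started on or
#' after the onset date is excluded.
#'
#' @param exposure A [drug_exposure()].
#' @param index_date Reaction onset date.
#' @return A `chronology_finding` with `latency_days`, `overlap`, and
#'   `compatibility`.
#' @export
assess_chronology_sefv <- function(exposure, index_date) {
  index_date <- .as_date(index_date, "index_date")
  .chronology_finding(exposure, index_date, function(lat) {
    if (lat <= 7L) "compatible"
    else if (lat <= 21L) "partially_compatible"
    else "incompatible"
  })
}

#' DRESS-specific chronology assessment
#'
#' DRESS symptoms typically appear two to eight weeks after the drug is
#' introduced, so the windows differ sharply from the general-purpose SEFV
#' ones: 15-56 days is compatible, 8-14 or 57-90 days partially
#' compatible, 1-7 days or beyond 90 days incompatible, and a drug
#' started on or after onset is excluded.
#'
#' @inheritParams assess_chronology_sefv
#' @return A `chronology_finding`.
#' @export
assess_chronology_aldress <- function(exposure, index_date) {
  index_date <- .as_date(index_date, "index_date")
  .chronology_finding(exposure, index_date, function(lat) {
    if (lat <= 7L) "incompatible"
    else if (lat <= 14L) "partially_compatible"
    else if (lat <= 56L) "compatible"
    else if (lat <= 90L) "partially_compatible"
    else "incompatible"
  })
}
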