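# Controlled vocabularies shared across the package. Missingness is always an
# explicit level (unknown / not_recorded / not_done), never an absent field,
# so scoring rules can address it deterministically.

SEX_LEVELS <- c("male", "female")

AUTOIMMUNE_LEVELS <- c("none_or_unknown", "rheumatoid_arthritis",
                       "psoriatic_arthritis", "ankylosing_spondylitis", "other")

GROUP_LEVELS <- c("case", "control", "unlabeled")

NOTORIETY_LEVELS <- c("well_known", "occasionally_reported", "unknown")

DECHALLENGE_LEVELS <- c("improved_after_withdrawal", "not_improved",
                        "not_withdrawn", "unassessable")

RECHALLENGE_LEVELS <- c("positive", "negative", "not_done")

PATHOGENS <- c("HHV6", "EBV", "CMV", "HSV", "VZV", "parvovirus",
               "HCV", "HBV", "HIV", "mycobacteria")

MICRO_METHODS <- c("PCR", "immunoassay", "unspecified")

MICRO_RESULTS <- c("positive", "negative", "not_recorded")

TEST_RESULTS <- c("positive", "negative", "not_done")

YNU_LEVELS <- c("yes", "no", "unknown")

EOSINOPHILIA_LEVELS <- c("none", "moderate", "marked", "unknown")

BIOPSY_LEVELS <- c("yes", "no", "not_done")

COMPATIBILITY_LEVELS <- c("compatible", "partially_compatible",
                          "incompatible", "excluding")

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_enum <- function(value, levels, field, where = "") {
  if (length(value) != 1L || is.na(value) || !value %in% levels) {
    stop(sprintf("invalid value '%s' for field '%s'%s (expected one of: %s)",
                 as.character(value)[1], field,
                 if (nzchar(where)) paste0(" in ", where) else "",
                 paste(levels, collapse = ", ")), call. = FALSE)
  }
  value
}

.as_date <- function(x, field, where = "") {
  if (length(x) != 1L || is.na(x) || !nzchar(as.character(x))) {
    stop(sprintf("missing or invalid date for field '%s'%s", field,
                 if (nzchar(where)) paste0(" in ", where) else ""),
         call. = FALSE)
  }
  d <- tryCatch(as.Date(x), error = function(e) NA)
  if (is.na(d)) {
    stop(sprintf("cannot parse '%s' as an ISO-8601 date for field '%s'%s",
                 as.character(x), field,
                 if (nzchar(where)) paste0(" in ", where) else ""),
         call. = FALSE)
  }
  d
}

.as_date_or_na <- function(x, field, where = "") {
  if (is.null(x) || length(x) == 0L || is.na(x) || !nzchar(as.character(x))) {
    return(as.Date(NA))
  }
  .as_date(x, field, where)
}
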