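# Seeded generator of synthetic DRESS case-control cohorts. The marginal
# structure (group sizes, culprit-drug multinomial, demographics, onset
# latency, per-pathogen microbiology rates, LTT rates) mirrors the
# 37-patient validation population; per-drug attributes are drawn from
# "culprit-like" and "innocent-like" conditional distributions chosen so
# that the default ALDRESS table separates culprits from innocents
# perfectly, except for a configurable number of planted errors.

.DEFAULT_DRUG_COUNTS <- c(
  amoxicillin = 4, amoxicillin_clavulanic = 7, benznidazole = 1,
  carbamazepine = 7, cotrimoxazole = 5, eslicarbazepine = 1,
  lamotrigine = 9, phenytoin = 1, sulfasalazine = 2)

# (positive, negative, not_recorded) counts out of 37, per pathogen.
# HBV is not screened in the emulated population: always not_recorded.
.DEFAULT_MICRO_COUNTS <- list(
  HHV6 = c(0, 17, 20), EBV = c(4, 12, 21), CMV = c(7, 14, 16),
  HSV = c(4, 7, 26), VZV = c(2, 2, 33), parvovirus = c(1, 13, 23),
  HCV = c(0, 16, 21), HBV = c(0, 0, 37), HIV = c(0, 17, 20),
  mycobacteria = c(2, 2, 33))

.CONCOMITANT_POOL <- c("paracetamol", "omeprazole", "ibuprofen", "metamizole",
                       "furosemide", "enalapril", "atorvastatin",
                       "levofloxacin", "ceftriaxone", "allopurinol")

#' Cohort generation profile
#'
#' Bundles every tunable of the synthetic cohort generator. Defaults
#' emulate the validation population: 7 single-drug cases and 30
#' multi-drug controls; culprit drugs from the nine-drug frequency table
#' (lamotrigine 9/37 the most frequent); age 41.62 +/- 17.09 years
#' truncated to [16, 95]; 54.1% male; culprit latency with mean 23 days;
#' per-pathogen microbiology and LTT result rates as observed; and one
#' missed case plus two control false alarms planted so the default
#' ALDRESS table reproduces the observed confusion structure.
#'
#' @param n_cases,n_controls Group sizes (cases carry one exposure,
#'   controls two to four).
#' @param drug_freqs Named culprit-drug weights (normalised internally).
#' @param age_mean,age_sd Normal age model, truncated to [16, 95] years.
#' @param male_fraction Probability of male sex.
#' @param onset_mean_days,onset_sd_days Log-normal culprit latency model
#'   (days); culprit draws are conditioned on the DRESS-compatible window
#'   [15, 56] with the log-mean re-solved so the conditional mean equals
#'   `onset_mean_days`.
#' @param microbiology_rates Named list of `(positive, negative,
#'   not_recorded)` weights per pathogen.
#' @param ltt_rates Weights for `(positive, negative, not_done)` LTT
#'   results.
#' @param autoimmune_rates Named weights over autoimmune-history levels.
#' @param planted_error Integer pair `(case_miss_count,
#'   control_false_alarm_count)`: culprit exposures degraded and innocent
#'   exposures promoted so a correctly configured ALDRESS engine
#'   misclassifies exactly those patients.
#' @return A `cohort_profile` object.
#' @export
cohort_profile <- function(n_cases = 7L, n_controls = 30L,
                           drug_freqs = .DEFAULT_DRUG_COUNTS,
                           age_mean = 41.62, age_sd = 17.09,
                           male_fraction = 0.541,
                           onset_mean_days = 23, onset_sd_days = 10,
                           microbiology_rates = .DEFAULT_MICRO_COUNTS,
                           ltt_rates = c(positive = 3, negative = 17,
                                         not_done = 17),
                           autoimmune_rates = c(none_or_unknown = 33,
                                                rheumatoid_arthritis = 2,
                                                psoriatic_arthritis = 2,
                                                ankylosing_spondylitis = 1,
                                                other = 0),
                           planted_error = c(1L, 2L)) {
  n_cases <- as.integer(n_cases); n_controls <- as.integer(n_controls)
  stopifnot(n_cases >= 0L, n_controls >= 0L, n_cases + n_controls >= 1L)
  if (is.null(names(drug_freqs)) || any(!nzchar(names(drug_freqs))) ||
      any(drug_freqs < 0) || sum(drug_freqs) <= 0) {
    stop("drug_freqs must be named non-negative weights", call. = FALSE)
  }
  stopifnot(age_sd > 0, male_fraction >= 0, male_fraction <= 1,
            onset_mean_days > 15, onset_mean_days < 56, onset_sd_days > 0)
  if (!setequal(names(microbiology_rates), PATHOGENS)) {
    stop("microbiology_rates must name all ten pathogens", call. = FALSE)
  }
  planted_error <- as.integer(planted_error)
  if (length(planted_error) != 2L || anyNA(planted_error) ||
      any(planted_error < 0L)) {
    stop("planted_error must be two non-negative integers", call. = FALSE)
  }
  if (planted_error[1] > n_cases || planted_error[2] > n_controls) {
    stop(sprintf(
      "infeasible planted_error (%d, %d) for %d cases / %d controls",
      planted_error[1], planted_error[2], n_cases, n_controls),
      call. = FALSE)
  }
  structure(list(
    n_cases = n_cases, n_controls = n_controls,
    n_total = n_cases + n_controls,
    drug_freqs = drug_freqs / sum(drug_freqs),
    age_mean = age_mean, age_sd = age_sd, male_fraction = male_fraction,
    onset_mean_days = onset_mean_days, onset_sd_days = onset_sd_days,
    microbiology_rates = microbiology_rates,
    ltt_rates = ltt_rates / sum(ltt_rates),
    autoimmune_rates = autoimmune_rates / sum(autoimmune_rates),
    planted_error = planted_error
  ), class = "cohort_profile")
}

# Log-normal latency conditioned on [lo, hi]: sdlog from the coefficient of
# variation, meanlog solved so the truncated mean equals the target.
.latency_model <- function(mean, sd, lo = 15, hi = 56) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  tmean <- function(mu) {
    num <- exp(mu + sdlog^2 / 2) *
      (stats::pnorm((log(hi) - mu - sdlog^2) / sdlog) -
       stats::pnorm((log(lo) - mu - sdlog^2) / sdlog))
    den <- stats::plnorm(hi, mu, sdlog) - stats::plnorm(lo, mu, sdlog)
    num / den
  }
  mu <- stats::uniroot(function(m) tmean(m) - mean,
                       lower = log(2), upper = log(200))$root
  list(meanlog = mu, sdlog = sdlog, lo = lo, hi = hi)
}

.draw_latency <- function(model, n = 1L) {
  plo <- stats::plnorm(model$lo, model$meanlog, model$sdlog)
  phi <- stats::plnorm(model$hi, model$meanlog, model$sdlog)
  x <- stats::qlnorm(stats::runif(n, plo, phi), model$meanlog, model$sdlog)
  pmin(pmax(as.integer(round(x)), model$lo), model$hi)
}

.draw_age <- function(profile) {
  repeat {
    a <- stats::rnorm(1, profile$age_mean, profile$age_sd)
    if (a >= 16 && a <= 95) return(round(a, 1))
  }
}

.sample1 <- function(x, prob = NULL) {
  if (length(x) == 1L) return(x)
  sample(x, 1L, prob = prob)
}

.draw_regiscar <- function() {
  rg <- list(
    fever_ge_38_5 = .sample1(c("yes", "no"), c(0.85, 0.15)),
    lymphadenopathy = .sample1(c("yes", "no"), c(0.6, 0.4)),
    eosinophilia_grade = .sample1(c("moderate", "marked"), c(0.3, 0.7)),
    atypical_lymphocytes = .sample1(c("yes", "no"), c(0.5, 0.5)),
    skin_extent_gt50 = .sample1(c("yes", "no"), c(0.6, 0.4)),
    rash_suggestive = "yes",
    biopsy_suggestive = .sample1(c("yes", "not_done"), c(0.4, 0.6)),
    organs_involved = .sample1(1:3, c(0.5, 0.35, 0.15)),
    resolution_ge_15_days = .sample1(c("yes", "no"), c(0.75, 0.25)),
    alternative_causes_excluded = .sample1(c("yes", "unknown"), c(0.7, 0.3)))
  inputs <- do.call(regiscar_inputs, rg)
  # Every simulated patient is an included subject: bump the most DRESS-
  # typical findings until the RegiSCAR inclusion gate (> +2) is met.
  if (!meets_inclusion(regiscar_score(inputs))) {
    rg$eosinophilia_grade <- "marked"
    rg$lymphadenopathy <- "yes"
    rg$atypical_lymphocytes <- "yes"
    inputs <- do.call(regiscar_inputs, rg)
  }
  inputs
}

.draw_microbiology <- function(profile) {
  res <- vapply(PATHOGENS, function(p) {
    .sample1(MICRO_RESULTS, profile$microbiology_rates[[p]])
  }, character(1))
  met <- ifelse(res == "not_recorded", "unspecified",
                ifelse(stats::runif(length(res)) < 0.7, "PCR", "immunoassay"))
  list(result = res, method = met)
}

.micro_level_raw <- function(res) {
  if (any(res == "positive")) -2L
  else if (any(res == "negative")) 1L
  else 0L
}

.immuno_level_raw <- function(ltt, patch) {
  if (ltt == "positive") 3L
  else if (patch == "positive") 2L
  else if (ltt == "negative" || patch == "negative") -1L
  else 0L
}

#' Generate a synthetic DRESS case-control cohort
#'
#' Cases carry exactly one exposure (the culprit); controls carry two to
#' four, exactly one of which is the true culprit
#' (`is_culprit_truth`). Culprit exposures draw DRESS-typical attributes
#' (compatible latency, improvement after withdrawal, well-known
#' notoriety); innocent concomitants draw incompatible or marginal
#' latencies and weak notoriety. Exposures required to classify as related
#' are repaired deterministically (rechallenge upgraded, positive
#' microbiology flipped) whenever patient-level penalties would otherwise
#' hold the default ALDRESS net score at or below the positivity
#' threshold; `planted_error` degrades the configured number of case
#' culprits and promotes innocents in the configured number of controls so
#' the default engine misclassifies exactly those patients.
#'
#' The same seed and profile always yield the identical cohort.
#'
#' @param profile A [cohort_profile()].
#' @param seed Integer seed controlling all randomness.
#' @return A `cohort_simulation` list with `records` (validated
#'   [patient_record()]s), `seed`, and `profile`.
#' @examples
#' sim <- generate_cohort(cohort_profile(), seed = 42)
#' length(sim$records)
#' @export
generate_cohort <- function(profile = cohort_profile(), seed = 1L) {
  stopifnot(inherits(profile, "cohort_profile"))
  seed <- as.integer(seed)
  records <- withr::with_seed(seed, .generate_records(profile))
  structure(list(records = records, seed = seed, profile = profile),
            class = "cohort_simulation")
}

.generate_records <- function(profile) {
  n <- profile$n_total
  groups <- rep(c("case", "control"), c(profile$n_cases, profile$n_controls))
  miss_idx <- if (profile$planted_error[1] > 0)
    sample(seq_len(profile$n_cases), profile$planted_error[1]) else integer()
  fa_idx <- if (profile$planted_error[2] > 0)
    profile$n_cases + sample(seq_len(profile$n_controls),
                             profile$planted_error[2]) else integer()
  latmod <- .latency_model(profile$onset_mean_days, profile$onset_sd_days)
  lapply(seq_len(n), function(i) {
    .generate_patient(sprintf("P%03d", i), groups[i], profile, latmod,
                      degrade_culprit = i %in% miss_idx,
                      promote_innocent = i %in% fa_idx)
  })
}

.generate_patient <- function(id, group, profile, latmod,
                              degrade_culprit, promote_innocent) {
  index_date <- as.Date("2016-01-01") + sample.int(2922L, 1L) - 1L
  mic <- .draw_microbiology(profile)
  ltt <- .sample1(TEST_RESULTS, profile$ltt_rates)
  patch <- if (ltt == "positive") .sample1(c("positive", "negative"),
                                           c(2 / 3, 1 / 3))
           else .sample1(c("not_done", "negative"), c(0.85, 0.15))
  regisc <- .draw_regiscar()
  resolution <- index_date +
    if (regisc$resolution_ge_15_days == "yes") sample(15:45, 1L)
    else sample(5:14, 1L)

  culprit_drug <- .sample1(names(profile$drug_freqs), profile$drug_freqs)
  n_innocent <- if (group == "case") 0L else sample(1:3, 1L)
  innocent_drugs <- if (n_innocent > 0L)
    sample(setdiff(.CONCOMITANT_POOL, culprit_drug), n_innocent)
  else character()

  exposures <- vector("list", 1L + n_innocent)
  # Culprit attributes: DRESS-typical, or deliberately degraded for a
  # planted miss (marginal latency, weaker notoriety, never withdrawn).
  if (degrade_culprit) {
    lat <- sample(8:14, 1L)
    exposures[[1L]] <- list(drug = culprit_drug, latency = lat,
                            notoriety = "occasionally_reported",
                            dechallenge = "not_withdrawn", stop = NA,
                            rechallenge = "not_done", culprit = TRUE,
                            need_related = FALSE)
  } else {
    exposures[[1L]] <- list(drug = culprit_drug,
                            latency = .draw_latency(latmod),
                            notoriety = "well_known",
                            dechallenge = "improved_after_withdrawal",
                            stop = sample(0:2, 1L),
                            rechallenge = "not_done", culprit = TRUE,
                            need_related = TRUE)
  }
  for (j in seq_len(n_innocent)) {
    cls <- .sample1(c("short", "early_partial", "late_partial", "very_long",
                      "post_onset"), c(0.40, 0.15, 0.20, 0.15, 0.10))
    lat <- switch(cls, short = sample(1:7, 1L),
                  early_partial = sample(8:14, 1L),
                  late_partial = sample(57:90, 1L),
                  very_long = sample(91:180, 1L),
                  post_onset = -sample(0:5, 1L))
    dech <- if (cls == "post_onset") "not_withdrawn"
            else .sample1(c("not_withdrawn", "improved_after_withdrawal",
                            "unassessable"), c(0.5, 0.3, 0.2))
    exposures[[1L + j]] <- list(
      drug = innocent_drugs[j], latency = lat,
      notoriety = .sample1(c("unknown", "occasionally_reported"),
                           c(0.6, 0.4)),
      dechallenge = dech,
      stop = switch(dech, improved_after_withdrawal = sample(0:2, 1L),
                    unassessable = sample(2:6, 1L), NA),
      rechallenge = .sample1(c("not_done", "negative"), c(0.95, 0.05)),
      culprit = FALSE, need_related = FALSE)
  }
  if (promote_innocent) {
    j <- 1L + sample.int(n_innocent, 1L)
    exposures[[j]]$latency <- .draw_latency(latmod)
    exposures[[j]]$notoriety <- "well_known"
    exposures[[j]]$dechallenge <- "improved_after_withdrawal"
    exposures[[j]]$stop <- sample(0:2, 1L)
    exposures[[j]]$rechallenge <- "not_done"
    exposures[[j]]$need_related <- TRUE
  }

  # Repair pass: every exposure required to be related must clear the
  # default ALDRESS threshold (base chronology+dechallenge+notoriety = 7)
  # against the patient-level penalties it will incur. Rechallenge is
  # upgraded first; if the positive-microbiology penalty still pins the
  # net at or below 7, the patient's positive results are flipped to
  # negative (the conditional, "culprit-like" part of the fixture).
  notorieties <- vapply(exposures, function(e) e$notoriety, character(1))
  for (j in seq_along(exposures)) {
    e <- exposures[[j]]
    if (!e$need_related) next
    concom <- -as.integer(any(.NOTORIETY_RANK[notorieties[-j]] >=
                                .NOTORIETY_RANK[[e$notoriety]]))
    base <- 3L + 2L + 2L + concom + .immuno_level_raw(ltt, patch)
    if (base + .micro_level_raw(mic$result) <= 7L) {
      exposures[[j]]$rechallenge <- "positive"
      if (base + 3L + .micro_level_raw(mic$result) <= 7L) {
        mic$result[mic$result == "positive"] <- "negative"
      }
    }
  }

  order_idx <- sample(seq_along(exposures))
  exp_objs <- lapply(exposures[order_idx], function(e) {
    start <- index_date - e$latency
    drug_exposure(e$drug, start_date = start,
                  stop_date = if (is.na(e$stop)) NA else
                    max(start, index_date + e$stop),
                  notoriety = e$notoriety, dechallenge = e$dechallenge,
                  rechallenge = e$rechallenge, is_culprit_truth = e$culprit)
  })
  keep <- mic$result != "not_recorded"
  patient_record(
    patient_id = id,
    age = .draw_age(profile),
    sex = .sample1(SEX_LEVELS, c(profile$male_fraction,
                                 1 - profile$male_fraction)),
    autoimmune_history = .sample1(names(profile$autoimmune_rates),
                                  profile$autoimmune_rates),
    index_date = index_date,
    resolution_date = resolution,
    group = group,
    regiscar = regisc,
    microbiology = microbiology_results(PATHOGENS[keep], mic$method[keep],
                                        mic$result[keep]),
    immunology = immunology_result(ltt = ltt, patch_test = patch),
    exposures = exp_objs)
}

#' @export
print.cohort_simulation <- function(x, ...) {
  cat(sprintf(
    "<cohort_simulation> %d patients (%d cases / %d controls), seed %d\n",
    x$profile$n_total, x$profile$n_cases, x$profile$n_controls, x$seed))
  invisible(x)
}

#' Descriptive cohort summary
#'
#' Per-drug frequency table of the suspected (culprit) medications with
#' percentages to one decimal, demographic summary (mean and SD of age,
#' sex split), and mean time from culprit start to onset. When no
#' simulation ground truth is present, all exposures count as suspected.
#'
#' @param records List of `patient_record` objects (nonempty).
#' @return A `cohort_summary` with elements `drug_table` (columns `drug`,
#'   `n`, `percentage`), `n`, `n_cases`, `n_controls`, `age_mean`,
#'   `age_sd`, `male_percent`, `onset_mean_days`.
#' @export
summarize_cohort <- function(records) {
  if (length(records) == 0L) stop("cannot summarize an empty cohort",
                                  call. = FALSE)
  validate_cohort(records)
  suspected <- unlist(lapply(records, function(r) {
    truth <- vapply(r$exposures, function(e) isTRUE(e$is_culprit_truth),
                    logical(1))
    picks <- if (any(truth)) r$exposures[truth] else r$exposures
    vapply(picks, function(e) e$drug_name, character(1))
  }))
  latencies <- unlist(lapply(records, function(r) {
    truth <- vapply(r$exposures, function(e) isTRUE(e$is_culprit_truth),
                    logical(1))
    picks <- if (any(truth)) r$exposures[truth] else r$exposures
    vapply(picks, function(e) as.integer(r$index_date - e$start_date),
           integer(1))
  }))
  counts <- table(suspected)
  drug_table <- data.frame(
    drug = names(counts),
    n = as.integer(counts),
    percentage = round(100 * as.integer(counts) / sum(counts), 1),
    stringsAsFactors = FALSE)
  drug_table <- drug_table[order(drug_table$drug), , drop = FALSE]
  rownames(drug_table) <- NULL
  ages <- vapply(records, `[[`, numeric(1), "age")
  sexes <- vapply(records, `[[`, character(1), "sex")
  groups <- vapply(records, `[[`, character(1), "group")
  structure(list(
    drug_table = drug_table,
    n = length(records),
    n_cases = sum(groups == "case"),
    n_controls = sum(groups == "control"),
    age_mean = mean(ages),
    age_sd = stats::sd(ages),
    male_percent = 100 * mean(sexes == "male"),
    onset_mean_days = mean(latencies)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients (%d cases / %d controls)\n",
              x$n, x$n_cases, x$n_controls))
  cat(sprintf("Age %.2f +/- %.2f y; male %.1f%%; mean time to onset %.1f d\n",
              x$age_mean, x$age_sd, x$male_percent, x$onset_mean_days))
  cat("Suspected medication\tN\tPercentage (%)\n")
  for (i in seq_len(nrow(x$drug_table))) {
    cat(sprintf("%s\t%d\t%.1f\n", x$drug_table$drug[i], x$drug_table$n[i],
                x$drug_table$percentage[i]))
  }
  invisible(x)
}
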