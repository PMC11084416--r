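# Independent oracles used to check the package's statistics. Each is
# written as a direct, unoptimised computation (bisection on tail sums,
# explicit loops over contingency cells, full hypergeometric enumeration)
# so that agreement with the package implementations is a genuine
# cross-check, not a restatement.

# Clopper-Pearson by bisection on the exact binomial tail sums.
cp_bisect_oracle <- function(x, n, alpha = 0.05, tol = 1e-9) {
  upper_tail <- function(p) sum(dbinom(x:n, n, p))   # P(X >= x)
  lower_tail <- function(p) sum(dbinom(0:x, n, p))   # P(X <= x)
  bisect <- function(f, target, increasing) {
    lo <- 0; hi <- 1
    for (i in 1:80) {
      mid <- (lo + hi) / 2
      if ((f(mid) < target) == increasing) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  low <- if (x == 0) 0 else bisect(upper_tail, alpha / 2, increasing = TRUE)
  high <- if (x == n) 1 else bisect(lower_tail, alpha / 2,
                                    increasing = FALSE)
  c(low = low, high = high)
}

# Cohen's kappa with FCE asymptotic SE, computed with explicit loops
# straight from the contingency table.
kappa_loop_oracle <- function(tab, weighting = "unweighted") {
  n <- sum(tab); k <- nrow(tab)
  w <- matrix(0, k, k)
  for (i in 1:k) for (j in 1:k) {
    d <- abs(i - j) / max(k - 1, 1)
    w[i, j] <- switch(weighting,
                      unweighted = as.numeric(i == j),
                      linear = 1 - d,
                      quadratic = 1 - d^2)
  }
  p <- tab / n
  r <- numeric(k); cc <- numeric(k)
  for (i in 1:k) for (j in 1:k) {
    r[i] <- r[i] + p[i, j]; cc[j] <- cc[j] + p[i, j]
  }
  po <- 0; pe <- 0
  for (i in 1:k) for (j in 1:k) {
    po <- po + w[i, j] * p[i, j]
    pe <- pe + w[i, j] * r[i] * cc[j]
  }
  kappa <- (po - pe) / (1 - pe)
  wr <- numeric(k); wc <- numeric(k)
  for (i in 1:k) for (j in 1:k) {
    wr[i] <- wr[i] + cc[j] * w[i, j]
    wc[j] <- wc[j] + r[i] * w[i, j]
  }
  s <- 0
  for (i in 1:k) for (j in 1:k) {
    s <- s + p[i, j] * (w[i, j] - (wr[i] + wc[j]) * (1 - kappa))^2
  }
  v <- (s - (kappa - pe * (1 - kappa))^2) / (n * (1 - pe)^2)
  list(kappa = kappa, ase = sqrt(v))
}

# Two-sided Fisher p by full enumeration of tables at fixed margins.
fisher_enum_oracle <- function(tp, fn, fp, tn) {
  m1 <- tp + fn; m2 <- fp + tn; c1 <- tp + fp
  a_range <- max(0, c1 - m2):min(m1, c1)
  probs <- dhyper(a_range, m1, m2, c1)
  obs <- dhyper(tp, m1, m2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# A small labeled cohort built by hand: one textbook single-drug case and
# one two-drug control with ground truth.
make_mini_cohort <- function() {
  case <- patient_record(
    patient_id = "C01", age = 35, sex = "female",
    index_date = "2022-03-21", resolution_date = "2022-04-20",
    group = "case",
    regiscar = regiscar_inputs(
      fever_ge_38_5 = "yes", lymphadenopathy = "yes",
      eosinophilia_grade = "marked", atypical_lymphocytes = "yes",
      skin_extent_gt50 = "yes", rash_suggestive = "yes",
      organs_involved = 2, resolution_ge_15_days = "yes",
      alternative_causes_excluded = "yes"),
    microbiology = microbiology_results(
      c("CMV", "EBV"), c("PCR", "PCR"), c("negative", "negative")),
    immunology = immunology_result(),
    exposures = list(drug_exposure(
      "lamotrigine", start_date = "2022-02-26", stop_date = "2022-03-22",
      notoriety = "well_known", dechallenge = "improved_after_withdrawal",
      rechallenge = "not_done", is_culprit_truth = TRUE)))
  control <- patient_record(
    patient_id = "K01", age = 61, sex = "male",
    index_date = "2021-07-10", group = "control",
    regiscar = regiscar_inputs(
      fever_ge_38_5 = "yes", eosinophilia_grade = "marked",
      rash_suggestive = "yes", organs_involved = 1,
      resolution_ge_15_days = "yes", alternative_causes_excluded = "yes"),
    microbiology = microbiology_results("CMV", "PCR", "negative"),
    immunology = immunology_result(ltt = "negative"),
    exposures = list(
      drug_exposure("carbamazepine", start_date = "2021-06-05",
                    stop_date = "2021-07-11", notoriety = "well_known",
                    dechallenge = "improved_after_withdrawal",
                    rechallenge = "positive", is_culprit_truth = TRUE),
      drug_exposure("omeprazole", start_date = "2021-07-05",
                    notoriety = "unknown", dechallenge = "not_withdrawn",
                    is_culprit_truth = FALSE)))
  list(case, control)
}
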