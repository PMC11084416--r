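test_that("profiles validate their structural invariants", {
  p <- cohort_profile()
  expect_equal(p$n_total, 37L)
  expect_equal(p$n_cases + p$n_controls, p$n_total)
  expect_equal(sum(p$drug_freqs), 1)
  expect_equal(unname(p$drug_freqs["lamotrigine"]), 9 / 37)
  expect_error(cohort_profile(planted_error = c(8, 2)), "infeasible")
  expect_error(cohort_profile(planted_error = c(1, 31)), "infeasible")
  expect_error(cohort_profile(drug_freqs = c(1, 2)), "named")
})

test_that("generation is deterministic in the seed", {
  a <- generate_cohort(cohort_profile(), seed = 42)
  b <- generate_cohort(cohort_profile(), seed = 42)
  expect_identical(a, b)
  c_ <- generate_cohort(cohort_profile(), seed = 43)
  expect_false(identical(a$records, c_$records))
})

test_that("generated records satisfy every domain invariant", {
  sim <- generate_cohort(cohort_profile(), seed = 5)
  expect_silent(validate_cohort(sim$records))
  groups <- vapply(sim$records, `[[`, character(1), "group")
  expect_equal(sum(groups == "case"), 7L)
  expect_equal(sum(groups == "control"), 30L)
  for (r in sim$records) {
    n_exp <- length(r$exposures)
    truths <- vapply(r$exposures, `[[`, logical(1), "is_culprit_truth")
    expect_equal(sum(truths), 1L)  # exactly one culprit everywhere
    if (r$group == "case") expect_equal(n_exp, 1L)
    if (r$group == "control") expect_true(n_exp >= 2L && n_exp <= 4L)
    # every simulated patient passes the inclusion gate
    expect_true(meets_inclusion(regiscar_score(r$regiscar)))
  }
})

test_that("planted errors are recovered exactly by the default engine", {
  plans <- list(c(0, 0), c(1, 2), c(2, 1), c(3, 5), c(7, 0))
  for (plan in plans) {
    sim <- generate_cohort(cohort_profile(planted_error = plan), seed = 17)
    cm <- evaluate_algorithm(sim$records)$confusion
    expect_equal(cm$fn, plan[1], label = paste("fn for", plan[1], plan[2]))
    expect_equal(cm$fp, plan[2], label = paste("fp for", plan[1], plan[2]))
    expect_equal(cm$tp, 7L - plan[1])
    expect_equal(cm$tn, 30L - plan[2])
  }
})

test_that("culprit drug frequencies follow the configured multinomial", {
  # 50x the default cohort size; lamotrigine expectation 9/37
  prof <- cohort_profile(n_cases = 350, n_controls = 1500,
                         planted_error = c(0, 0))
  sim <- generate_cohort(prof, seed = 23)
  culprits <- vapply(sim$records, function(r) {
    truths <- vapply(r$exposures, `[[`, logical(1), "is_culprit_truth")
    r$exposures[truths][[1]]$drug_name
  }, character(1))
  n <- length(culprits)
  p0 <- 9 / 37
  se <- sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(mean(culprits == "lamotrigine") - p0), 3 * se)
})

test_that("mean onset latency across seeds matches the configured 23 days", {
  m <- vapply(1:200, function(s) {
    summarize_cohort(generate_cohort(cohort_profile(), seed = s)$records)$onset_mean_days
  }, numeric(1))
  expect_lt(abs(mean(m) - 23), 1)
})

test_that("summaries reproduce the frequency-table arithmetic", {
  sim <- generate_cohort(cohort_profile(), seed = 31)
  s <- summarize_cohort(sim$records)
  expect_equal(s$n, 37L)
  expect_equal(sum(s$drug_table$n), 37L)
  expect_lte(abs(sum(s$drug_table$percentage) - 100), 0.2)
  # a cohort with 9 of 37 lamotrigine culprits prints 24.3%
  counts <- s$drug_table
  if ("lamotrigine" %in% counts$drug) {
    k <- counts$n[counts$drug == "lamotrigine"]
    expect_equal(counts$percentage[counts$drug == "lamotrigine"],
                 round(100 * k / 37, 1))
  }
  expect_equal(round(100 * 9 / 37, 1), 24.3)
  # single-patient cohort: its drug at 100.0%
  s1 <- summarize_cohort(sim$records[1])
  expect_equal(s1$drug_table$percentage, 100)
  expect_error(summarize_cohort(list()), "empty")
})

test_that("microbiology and LTT marginals track the configured rates", {
  prof <- cohort_profile(n_cases = 350, n_controls = 1500,
                         planted_error = c(0, 0))
  sim <- generate_cohort(prof, seed = 29)
  n <- length(sim$records)
  ltt <- vapply(sim$records, function(r) r$immunology$ltt, character(1))
  expect_lt(abs(mean(ltt == "negative") - 17 / 37),
            3 * sqrt((17 / 37) * (20 / 37) / n))
  hhv6 <- vapply(sim$records, function(r)
    r$microbiology$result[r$microbiology$pathogen == "HHV6"], character(1))
  # HHV6 is never positive in the emulated population
  expect_false(any(hhv6 == "positive"))
  cmv <- vapply(sim$records, function(r)
    r$microbiology$result[r$microbiology$pathogen == "CMV"], character(1))
  # the repair pass can flip a few positives to negative, so allow a
  # one-sided slack below the configured 7/37 rate
  expect_lt(mean(cmv == "positive"), 7 / 37 + 3 * sqrt((7 / 37) * (30 / 37) / n))
  expect_gt(mean(cmv == "positive"), 0.05)
})
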