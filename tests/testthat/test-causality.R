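exposure_at <- function(latency, ...) {
  drug_exposure("testdrug", start_date = as.Date("2022-06-01") - latency, ...)
}
index <- as.Date("2022-06-01")

test_that("SEFV chronology windows: 1-7 compatible, 8-21 partial, >21 no", {
  cases <- list(list(4, "compatible"), list(1, "compatible"),
                list(7, "compatible"), list(8, "partially_compatible"),
                list(14, "partially_compatible"),
                list(21, "partially_compatible"),
                list(22, "incompatible"), list(120, "incompatible"))
  for (cs in cases) {
    f <- assess_chronology_sefv(exposure_at(cs[[1]]), index)
    expect_equal(f$compatibility, cs[[2]], label = paste("latency", cs[[1]]))
    expect_equal(f$latency_days, cs[[1]])
  }
  expect_equal(assess_chronology_sefv(exposure_at(-1), index)$compatibility,
               "excluding")
  expect_equal(assess_chronology_sefv(exposure_at(-1), index)$overlap,
               "onset_before_start")
})

test_that("DRESS chronology windows follow the 2-8 week typical latency", {
  cases <- list(list(23, "compatible"), list(15, "compatible"),
                list(56, "compatible"), list(10, "partially_compatible"),
                list(8, "partially_compatible"), list(14, "partially_compatible"),
                list(57, "partially_compatible"), list(90, "partially_compatible"),
                list(7, "incompatible"), list(1, "incompatible"),
                list(120, "incompatible"), list(91, "incompatible"))
  for (cs in cases) {
    expect_equal(assess_chronology_aldress(exposure_at(cs[[1]]),
                                           index)$compatibility,
                 cs[[2]], label = paste("latency", cs[[1]]))
  }
  expect_equal(assess_chronology_aldress(exposure_at(0), index)$compatibility,
               "excluding")
})

test_that("shipped tables load with the published structure", {
  sefv <- default_score_table("sefv")
  expect_length(sefv$items, 7L)
  expect_equal(sefv$positivity_threshold, 6L)
  ald <- default_score_table("aldress")
  expect_equal(ald$positivity_threshold, 7L)
  expect_length(ald$items, 7L)
})

test_that("band gaps, overlaps, and unknown levels are configuration errors", {
  cfg <- yaml::read_yaml(system.file("extdata", "sefv.yaml",
                                     package = "aldress"))
  broken <- cfg
  broken$bands[[1]]$max <- -2  # leaves -1..0 uncovered
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(broken, path)
  expect_error(load_score_table(path), "gap or overlap")
  broken2 <- cfg
  broken2$bands[[1]]$min <- -5  # -7..-6 reachable but uncovered
  yaml::write_yaml(broken2, path)
  expect_error(load_score_table(path), "cover reachable scores")
  tab <- default_score_table("sefv")
  expect_error(aldress:::.score_items(list(chronology = "instant"), tab),
               "level 'instant'")
})

textbook_case <- function() make_mini_cohort()[[1]]

test_that("a textbook single-drug case nets 8 under ALDRESS and is related", {
  rec <- textbook_case()
  a <- score_drug(rec, rec$exposures[[1]], default_score_table("aldress"))
  # chronology compatible +3, dechallenge improved +2, notoriety +2,
  # screens negative +1, LTT not done 0, rechallenge not done 0
  expect_equal(unname(a$per_item_points[c("chronology", "dechallenge",
                                          "notoriety", "alternative_cause",
                                          "immunology", "rechallenge",
                                          "concomitant")]),
               c(3L, 2L, 2L, 1L, 0L, 0L, 0L))
  expect_equal(a$net_score, 8L)
  expect_true(a$related)
  expect_equal(a$net_score, sum(a$per_item_points))
})

test_that("adding non-positive findings can only lower the net score", {
  rec <- textbook_case()
  worse <- rec
  worse$immunology <- immunology_result(ltt = "negative")
  worse$microbiology <- microbiology_results("CMV", "PCR", "positive")
  a0 <- score_drug(rec, rec$exposures[[1]])
  a1 <- score_drug(worse, worse$exposures[[1]])
  expect_lt(a1$net_score, a0$net_score)
})

test_that("the RegiSCAR gate blocks ALDRESS scoring and names the score", {
  rec <- textbook_case()
  rec$regiscar <- regiscar_inputs(rash_suggestive = "yes",
                                  eosinophilia_grade = "moderate") # total +2
  err <- expect_error(score_drug(rec, rec$exposures[[1]],
                                 default_score_table("aldress")),
                      "RegiSCAR inclusion gate")
  expect_match(conditionMessage(err), "\\+2")
  # SEFV carries no gate
  expect_no_error(score_drug(rec, rec$exposures[[1]],
                             default_score_table("sefv")))
})

test_that("positivity thresholds are strict for both algorithms", {
  for (algo in c("aldress", "sefv")) {
    tab <- default_score_table(algo)
    thr <- tab$positivity_threshold
    expect_false(classify(thr, tab)$related)
    expect_true(classify(thr + 1L, tab)$related)
  }
  sefv <- default_score_table("sefv")
  expect_false(classify(6L, sefv)$related)
  expect_equal(classify(0L, sefv)$category, "unlikely")
  expect_equal(classify(-3L, sefv)$category, "unlikely")
  expect_false(classify(0L, sefv, binary = "category")$related)
  ald <- default_score_table("aldress")
  expect_false(classify(7L, ald)$related)
  expect_true(classify(8L, ald)$related)
})

test_that("threshold and category binary rules disagree only where expected", {
  sefv <- default_score_table("sefv")
  for (s in sefv$min_score:sefv$max_score) {
    thr <- classify(s, sefv, "threshold")$related
    cat_ <- classify(s, sefv, "category")$related
    if (s >= 4 && s <= 6) {
      expect_true(cat_ && !thr)  # possible/probable band below the cutoff
    } else {
      expect_equal(thr, cat_)
    }
  }
})

test_that("the engine is table-agnostic: swapping tables swaps the scoring", {
  rec <- textbook_case()
  e <- rec$exposures[[1]]
  ald <- score_drug(rec, e, default_score_table("aldress"))
  sefv <- score_drug(rec, e, default_score_table("sefv"))
  expect_named(sefv$per_item_points,
               c("chronology", "literature", "withdrawal", "rechallenge",
                 "alternative_causes", "contributing_factors",
                 "complementary_explorations"))
  # same clinical facts, different windows: the 23-day latency is DRESS-
  # compatible (+3) but beyond the SEFV 21-day limit (0)
  expect_equal(ald$per_item_points[["chronology"]], 3L)
  expect_equal(sefv$per_item_points[["chronology"]], 0L)
  # custom table with the aldress deriver but rescaled points
  cfg <- yaml::read_yaml(system.file("extdata", "aldress.yaml",
                                     package = "aldress"))
  cfg$items[[1]]$levels$compatible <- 5
  cfg$bands[[4]]$max <- 16
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  custom <- load_score_table(path)
  expect_equal(score_drug(rec, e, custom)$net_score, ald$net_score + 2L)
})

test_that("missing clinical information is always score-neutral", {
  for (tab in list(default_score_table("aldress"),
                   default_score_table("sefv"))) {
    for (it in tab$items) {
      for (lev in intersect(names(it$levels),
                            c("unknown", "not_done", "not_recorded",
                              "unassessable", "not_withdrawn"))) {
        expect_equal(it$levels[[lev]], 0L,
                     label = paste(tab$algorithm, it$id, lev))
      }
    }
  }
})

test_that("assess_cohort yields one assessment per patient-drug pair", {
  recs <- make_mini_cohort()
  df <- assess_cohort(recs, default_score_table("aldress"))
  expect_equal(nrow(df), 3L)
  expect_equal(df$patient_id, c("C01", "K01", "K01"))
  expect_equal(df$net_score, rowSums(df[, c("chronology", "dechallenge",
                                            "rechallenge", "notoriety",
                                            "alternative_cause", "immunology",
                                            "concomitant")]))
  # repeated episodes of one drug collapse to the most compatible episode
  rec <- recs[[1]]
  rec$exposures <- list(
    rec$exposures[[1]],
    drug_exposure("lamotrigine", start_date = "2022-03-19",
                  notoriety = "well_known",
                  dechallenge = "improved_after_withdrawal"))
  rec$group <- "unlabeled"
  df2 <- assess_cohort(list(rec), default_score_table("aldress"))
  expect_equal(nrow(df2), 1L)
  expect_equal(df2$chronology, 3L)  # the compatible episode wins
})

test_that("gate failures during batch scoring can be skipped with warning", {
  recs <- make_mini_cohort()
  recs[[1]]$regiscar <- regiscar_inputs(rash_suggestive = "yes") # total +1
  expect_error(assess_cohort(recs, default_score_table("aldress")),
               "RegiSCAR inclusion gate")
  expect_warning(
    df <- assess_cohort(recs, default_score_table("aldress"),
                        on_gate_failure = "skip"),
    "skipped 1 patient")
  expect_false("C01" %in% df$patient_id)
})
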