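---
title: "Methods: causality scoring, validation statistics, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: causality scoring, validation statistics, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aldress)
```

## The problem

Drug reaction with eosinophilia and systemic symptoms (DRESS) is a severe
delayed hypersensitivity syndrome — rash, fever, eosinophilia, and visceral
involvement appearing typically two to eight weeks after a drug is
introduced. Because patients are often on several drugs when the reaction
declares itself, deciding *which* drug caused it is both crucial (the
culprit must be withdrawn and avoided for life; the innocents should stay
available) and hard. General-purpose pharmacovigilance algorithms embed
latency windows of days, not weeks, and so fit DRESS poorly.

This package implements a DRESS-specific causality score (ALDRESS)
alongside the general Spanish Pharmacovigilance System algorithm (SEFV) and
the RegiSCAR diagnostic score that gates inclusion, plus the full
statistical machinery used to validate such an algorithm on a case-control
cohort: diagnostic accuracy with exact binomial confidence intervals,
Fisher's exact test, and Cohen's kappa agreement analysis.

## The scoring model

All three instruments share one declarative engine. A *score table* (a YAML
config; see `default_score_table()`) lists items, each mapping clinical
levels to integer points; a net score is the sum of the item points; a
strict positivity threshold converts it to a binary call (`related` iff
`net > threshold`); contiguous category bands, validated to cover the
analytic score range exactly, give the qualitative reading. The engine is
table-agnostic: ALDRESS and SEFV differ only in their config and in the
deriver that turns a patient record into item levels.

### Item derivation

- **Chronology.** Latency is `index_date - start_date` in whole days
  (day 0 = started the day of onset). ALDRESS uses the DRESS-typical
  windows: 15–56 d compatible, 8–14 or 57–90 d partially compatible, 1–7 or
  >90 d incompatible. SEFV uses its published general windows: 1–7 d
  compatible, 8–21 d partially compatible, >21 d incompatible. In both, a
  drug started on or after the onset date is *excluding*. The two window
  sets are deliberately not reconciled: each belongs to its algorithm.
- **Dechallenge / rechallenge / notoriety** come directly from the
  exposure record.
- **Alternative infectious cause.** Any positive pathogen in the
  microbiology screen (herpesviruses, hepatitis viruses, HIV, parvovirus,
  mycobacteria) counts against the drug; a screen with at least one
  negative result and no positives supports it; no recorded work-up is
  neutral.
- **Immunology (ALDRESS).** A positive LTT scores +3; failing that a
  positive patch test +2 (so combined serological support is capped at +3);
  a negative work-up −1; not done 0.
- **Concomitant penalty (ALDRESS).** A drug loses one point when another
  suspect in the same patient carries at least equal notoriety — the
  situation observers found hardest to score consistently.

Missing information (`unknown`, `not_done`, `not_recorded`,
`not_withdrawn`, `unassessable`) always maps to 0 points in the shipped
tables, so incomplete records — common in retrospective data — are
score-neutral rather than silently penalised.

### The ALDRESS point allocation is a convention

The published description of ALDRESS fixes its domains, its RegiSCAR > +2
inclusion gate, and its positivity rule (score > 7), but not the per-item
points. The table shipped here (chronology +3/+1/−3/−4, dechallenge
+2/−2/0, rechallenge +3/−2/0, notoriety +2/+1/0, alternative cause
−2/+1/0, immunology +3/+2/−1/0, concomitant −1/0) is therefore this
package's own documented convention, constrained so that (a) positivity is
strictly `> 7` and (b) a textbook single-drug case — compatible chronology,
improvement on withdrawal, well-known drug, negative infectious screen —
nets 8 and classifies as related. It must not be cited as the original
authors' allocation, and it is fully overridable via `load_score_table()`.

Two binary readings are supported: the threshold rule (default, the one
the validation metrics are defined by) and the category rule
(related = possible/probable/definite). For SEFV these disagree at scores
4–6; the threshold rule wins by default.

### RegiSCAR

The RegiSCAR table ships the standard validation-score points (fever
no/unknown −1, lymphadenopathy +1, eosinophilia +1/+2, atypical
lymphocytes +1, extent >50% +1, suggestive rash +1 / non-suggestive −1,
non-suggestive biopsy −1, organ involvement +1/+2, resolution <15 d −1,
≥3 alternatives excluded +1) with bands ≤+1 excluded, +2..+3 possible, +4
probable, ≥+5 definite. The band map follows the wording the validation
study used (+4 probable, ≥+5 definite) rather than the 4–5/>5 variant in
the older literature; both are config-overridable. The analytic maximum of
the shipped table is +9; the definite band is open-ended above +5 rather
than clamped.

## Validation statistics

- **Diagnostic accuracy.** Sensitivity, specificity, PPV, NPV, and accuracy
  each carry a Clopper–Pearson exact interval (beta-quantile inversion of
  the binomial tails; the method is pinned by reproducing the published
  intervals, e.g. 6/7 → 0.4213–0.9964). The positive likelihood ratio is
  computed from the *unrounded* sensitivity and specificity and carries no
  interval. A metric with a zero denominator is reported as undefined,
  never as 0. Fisher's exact test uses the conventional two-sided rule
  (sum of hypergeometric probabilities ≤ the observed table's), without
  mid-p.
- **Agreement.** `percent_agreement()` is the exact-match fraction.
  `cohen_kappa()` implements the weighted kappa with the
  Fleiss–Cohen–Everitt large-sample standard error *under the
  alternative*; that single ASE drives the z statistic, the two-sided
  normal p, and the Wald interval, because the published rows are
  consistent with exactly that relation (0.5761/0.1307 = 4.41;
  0.5761 ± 1.96·0.1307 = 0.320–0.832). The weighting scheme behind
  published "weighted" rows is generally unstated; the default here is
  quadratic weights `1 - ((i-j)/(k-1))^2`, with linear available, and on
  binary ratings every scheme collapses to the unweighted kappa — a
  property the published agreement table itself exhibits. Landis–Koch
  bands: <0.10 none, 0.10–0.20 slight, 0.21–0.40 fair, 0.41–0.60 moderate,
  0.61–0.80 substantial, ≥0.81 near perfect.

## Patient-level evaluation contract

The validation population contains 7 *cases* (the culprit was the only
drug given — the closest thing to ground truth DRESS causality offers) and
30 *controls* (several suspects, exactly one of which is the planted/known
culprit). `evaluate_algorithm()` reduces per-drug calls to one call per
patient:

- a **case** is predicted positive when its single drug is called related
  (a miss is the false negative);
- a **control** is predicted positive when the algorithm *wrongly
  implicates an innocent* concomitant (the false positive). Correctly
  flagging a control's true culprit is correct behaviour, not a false
  alarm, which is why controls require per-drug `is_culprit_truth` labels.

This yields a 7-positive / 30-negative confusion matrix, the unit of
analysis the validation metrics are defined on.

## The synthetic cohort generator

`generate_cohort()` emulates the validation population's *marginals*, not
its patients: 7 cases / 30 controls; culprit drugs from the nine-drug
multinomial (lamotrigine 9/37, amoxicillin–clavulanic acid and
carbamazepine 7/37 each, ...); age normal 41.62 ± 17.09 y truncated to
[16, 95] (the published "median 41.62 ± 17.09" is treated as mean ± SD);
54.1% male; per-pathogen microbiology rates as observed (e.g. CMV 7/37
positive, 14/37 negative, 16/37 unrecorded; hepatitis B is never screened);
LTT 3 positive / 17 negative / 17 not done (the published counts sum to
33 of 37; the four unaccounted patients are folded into *not done*); and
autoimmune history from the published counts normalised (they sum to 38,
an internal inconsistency of the source table; counts are taken as
authoritative over the printed percentages throughout).

Culprit latency is log-normal with configured mean 23 d and SD 10 d,
*conditioned on the DRESS-compatible window [15, 56]*, with the log-mean
re-solved numerically so the conditional mean still equals 23 d. The
conditioning (rather than the wider [1, 90] truncation one would use for a
purely descriptive simulation) is forced by the generator's separation
contract below; across seeds the realised mean onset stays within one day
of 23 (the one degraded culprit per cohort draws 8–14 d).

**Separation contract.** Culprit-like and innocent-like attribute
distributions are fixtures chosen so the default ALDRESS table separates
them perfectly absent planted error — they are a test harness contract,
*not* a claim about the real cohort. Innocent concomitants draw weak
notoriety, marginal or incompatible latencies, and neutral dechallenge,
which analytically caps their net at 7 (never related). Exposures required
to be related start from the base compatible + improved + well-known = 7
and are repaired deterministically against patient-level penalties:
rechallenge is upgraded to positive when a positive pathogen, negative
LTT, or concomitant penalty would pin the net at ≤ 7, and the patient's
positive microbiology is flipped to negative in the one combination
(positive screen plus negative immunology) that rechallenge alone cannot
lift above the threshold. These conditionals perturb the microbiology
marginals slightly in culprit-bearing patients. RegiSCAR inputs are drawn
DRESS-typical and bumped when a draw would fail the > +2 gate, so every
simulated patient is an includable subject.

`planted_error = c(a, b)` (default `c(1, 2)`, the misclassification
pattern the validation study observed) degrades `a` case culprits
(marginal 8–14 d latency, weaker notoriety, never withdrawn — analytic
maximum 6) and promotes one innocent in each of `b` controls through the
same required-related repair. The end-to-end recovery `fn = a, fp = b`,
exactly, for every feasible `(a, b)`, is property-tested and is what makes
the generator a usable oracle for the whole pipeline.

What the generator does *not* emulate: record-level correlation structure
(organ patterns by drug class, age–drug interactions), multi-episode
exposures, real rechallenge prevalence (rechallenge is upgraded as a
repair lever more often than clinical reality would show), and secular
dating. Passing tests on synthetic cohorts therefore demonstrate the
correctness of the scoring and evaluation machinery under the published
marginal conditions, not field performance of the algorithm.

## Numerical choices and problem sizes

- Intervals: Clopper–Pearson via `qbeta`, degenerate bounds exact
  (x = 0 → 0, x = n → 1); cross-checked against tail-sum bisection to
  1e-6 for all n ≤ 30.
- Kappa: undefined (explicit error) when both raters are confined to one
  category (expected agreement 1); the ASE formula is checked against a
  loop-based oracle to 1e-10 and against independent reference values on a
  fixed 3×3 table.
- The latency log-mean solve uses `uniroot` on the closed-form truncated
  log-normal mean; ages are drawn by rejection.
- Same-drug multiple episodes: the episode with the most compatible
  chronology is scored, one assessment per (patient, drug).
- Test problem sizes: the cross-seed onset check averages 200 cohorts; the
  frequency checks use 50× cohorts (1850 patients); threshold strictness
  is checked over 1000 random tables; planting recovery over 20 seeds and
  five error patterns.

## Known limitations

- The ALDRESS point allocation is a reasoned convention (above), so
  absolute net scores are comparable only within a config.
- The SEFV validation metrics published alongside the ALDRESS ones are
  internally inconsistent (the printed likelihood ratio does not follow
  from the printed sensitivity and specificity) and their underlying
  counts are not reconstructible; the package reproduces the ALDRESS
  suite and covers SEFV by the same engine properties instead.
- Inter-observer agreement requires two raters' vectors, which no
  published source provides; the kappa machinery is validated by oracle
  properties, not by reproducing those tables.
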