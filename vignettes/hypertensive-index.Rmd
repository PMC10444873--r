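---
title: "The Hypertensive Index: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Hypertensive Index: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htindex)
```

## The measurement problem

Trials of device-based (non-pharmacological) treatment of hypertension have
two endpoints that trade off against each other: the achieved blood pressure
and the number of antihypertensive drugs needed to achieve it. Reporting
either alone understates benefit — a patient discharged on fewer drugs at the
same pressure has clearly improved, yet shows no blood-pressure change. The
Hypertensive Index (HTi) folds both into one number:

$$\mathrm{HTi} = (\mathrm{SBP} - 120)\times(n_\mathrm{meds} + 1)$$

with SBP the systolic pressure in mmHg and $n_\mathrm{meds}$ the count of
distinct prescribed antihypertensive agents. The reference of 120 mmHg is the
guideline ideal systolic pressure, so the first factor is the *excess*
pressure; the offset of 1 keeps the multiplier nonzero for patients on no
medication. At exactly 120 mmHg the score is 0 whatever the drug count, and
below 120 it is negative — a deliberate property flagging possible
over-treatment rather than a defect. Because risk from excess pressure is
approximately linear, the product reads as "excess pressure, scaled by the
pharmacological effort needed to hold it there".

```{r}
hti(145, 2)   # 145 mmHg on two drugs
hti(130, 4)   # lower pressure bought with four drugs scores *less*
```

## Parameters and conventions

* **`bp_reference` (default 120 mmHg).** The systolic ideal. Variant
  components default to their value at an ideal 120/80 reading: 80 for
  diastolic, $80 + 40/3 \approx 93.3$ for mean arterial pressure (one-third
  rule, $\mathrm{DBP} + (\mathrm{SBP}-\mathrm{DBP})/3$), 40 for pulse
  pressure. No authoritative reference values exist for the variants, so
  these are package conventions, configurable in `hti_definition()`.
* **`med_offset` (default 1).** Must be at least 1; see above.
* **Medication count.** The number of distinct prescribed agents; a
  fixed-dose combination pill counts as the agents it contains. Non-integer
  counts in patient-level data are rejected, never rounded — silent coercion
  hides data errors. Dose-weighted loads (e.g. defined daily doses) are out
  of scope.
* **Comparator.** `gwas_score()` implements the treated-blood-pressure
  phenotype used in large genetic studies: SBP plus a flat 10 mmHg if *any*
  antihypertensive is prescribed.

## Response classification

Between baseline and discharge, a *significant* blood-pressure change is a
drop of ≥ 20 mmHg systolic or ≥ 10 mmHg diastolic (inclusive thresholds).
Crossing that with whether the medication count decreased gives four groups:
1 (BP↓, drugs↓), 2 (BP↓, drugs not reduced), 3 (BP↔, drugs↓), 4 (BP↔, drugs
not reduced). "Not reduced" pools unchanged and increased counts so the
groups partition every cohort. A *successful* intervention is a significant
BP change without added medication, or any medication reduction without a
rise in systolic pressure (ties allowed). Two open choices were resolved as
follows and are isolated in `is_success()`:

* the "no rise in blood pressure" clause is evaluated on systolic pressure
  only, since the index and the headline analyses are systolic-based;
* success is computed from its own definition, not derived from the group
  label, so "BP improved but medications added" is Group 2 yet *not* a
  success.

## ROC comparison

`roc_curve()` scores each candidate improvement measure (all oriented as
baseline − discharge, so larger is always better, including medication load)
against the success label. The AUC is the rank (concordant-pair) statistic —
the probability that a random success outranks a random failure, ties
credited one half — rather than trapezoidal integration of the empirical
curve; the two agree under the tie convention, and the rank form is directly
testable against exhaustive pair counting. Operating points are reported at
every distinct threshold plus sentinels. Degenerate label vectors (one class
only) are an error, not an NA: an AUC is undefined there and downstream
averaging should fail loudly. No confidence intervals or DeLong tests are
computed; comparisons are point estimates only.

## The synthetic cohort generator

No patient-level data accompany the index, so `generate_cohort()` simulates
cohorts from the published group-level moments (`hti_group_moments()`): four
response groups of 46/29/15/9 patients with per-group baseline/discharge
means and sds for SBP, DBP and medication count. The generative model, per
group:

* baseline and discharge SBP are bivariate normal with the group's margins
  and correlation `rho = 0.8`; DBP likewise, independent of SBP given the
  group. Within-patient blood-pressure tracking is strong, and 0.8 makes the
  spread of within-patient change compatible with the published discharge
  spreads; the moments themselves carry no covariance information, so `rho`
  is exposed in the configuration.
* medication counts are rounded normals truncated at zero (the published
  sds are far below Poisson variance, ruling out count models); groups 1 and
  3 draw a discharge count strictly below baseline, groups 2 and 4 reuse the
  baseline count unchanged.
* each candidate is rejection-sampled until it re-classifies into its
  intended group, with a cap (default 10,000 attempts per patient, enforced
  as a per-group budget) whose breach signals an infeasible specification.
  Group sizes are stratified and exact, not multinomial, so the published
  group sizes are reproduced at every seed.

**What the generator does and does not emulate.** It reproduces the group
structure, the group moments (see below), the pooled contrasts (all four
variables fall, pooled paired p < 0.0001), a strongly positive Spearman
correlation between baseline index and index improvement, and a mean ΔHTi
AUC close to the published value. It does *not* contain patients whose
medication count rises (groups 2 and 4 are constructed with unchanged
counts): real "BP improved but drugs added" patients are hard negatives for
the ΔSBP and comparator scores, and their absence makes those predictors
look better here than they do on real data — so the published *ordering* of
AUCs (index above systolic pressure alone) is not reproduced by these
simulations, while the index's own AUC is. Passing simulation tests
therefore validates the scoring, classification and ROC machinery, not the
clinical superiority claim. SBP–DBP cross-correlation within group is also
not modelled (the group structure already induces a cohort-level
association).

**Rejection bias.** Conditioning groups 3–4 on "no significant BP change"
truncates the upper tail of the within-patient drop, pulling the generated
baseline SBP means a few mmHg below their targets (the discharge means a
little above). Groups 1–2 are essentially unbiased, since for them rejection
is a rare event. The test suite verifies recovery of all group means at
×10 scale — within 3 standard errors for groups 1–2 and within a 10 mmHg
fidelity bound for groups 3–4, the bound documenting this known truncation
bias.

## Summary tables and test selection

`paired_comparison()` gates on a Shapiro–Wilk test of the within-patient
differences at α = 0.05 (the gate level is a `test_policy()` parameter):
compatible with normality → paired t-test; otherwise the Wilcoxon
signed-rank test, the paired analogue of the Mann–Whitney U test (Welch and
Mann–Whitney proper serve unpaired, between-group contrasts). Samples beyond
the Shapiro–Wilk range (n > 5000) are treated as normal, where the t-test is
robust anyway. The rank branch is validated against an exhaustive sign-flip
permutation oracle at small n. Zero-variance differences and n < 3 are
errors at the single-comparison level, reported as NA p-values (with the
reason in `test_name`) when they occur inside a larger summary table, so one
degenerate subgroup cannot sink a whole report.

`summary_table()` reports per-timepoint centers with t-based 95% CI
half-widths of the mean; the center switches from mean to median when the
normality gate fails, and the choice is recorded per row. Per-group tables
summarise the index by its median and raw variables by mean (sd). Whether a
published per-timepoint "95% ci" column is a per-timepoint or
paired-difference interval is ambiguous in the source material (identical
widths at both timepoints suggest the latter); this package reports
per-timepoint half-widths and documents the discrepancy rather than guessing.
No multiple-testing correction is applied, matching the design being
reproduced.

A caution that follows from the algebra: the index is a product, so the
index of cohort means (`hti_from_summary()`, used to score external trials
from their published tables) is **not** the mean of per-patient indices.
Published whole-cohort index means can therefore not be checked from group
moments, only qualitatively via simulation.

## Problem sizes and numerical choices

Simulation-based checks use cohorts of n = 99 (the published group sizes),
200 seeds for AUC averaging, and a single ×10-scale cohort for moment
recovery — sizes chosen to make Monte-Carlo error small relative to the
tolerances being checked. CSV serialisation writes the shortest decimal that
round-trips each double exactly, so written cohorts re-read bit-identically.
All randomness flows through a single integer seed; identical configuration
and seed give byte-identical cohorts.

## Known limitations

* The generator's group-conditional normality and fixed `rho` are modelling
  conveniences, not estimates; only first and second moments are calibrated.
* Negative index scores are returned unchanged; interpreting them as
  over-treatment is a reading, not a validated calibration.
* The success rule's diastolic behaviour under medication reduction is
  unspecified in the source material; the systolic-only choice here is
  documented but untestable against data.
* No modelling of excluded perioperative deaths, partial revascularisation,
  drug classes, doses, adherence, or follow-up beyond discharge.
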