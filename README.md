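# htindex

Outcome reporting for device-based (non-pharmacological) treatment of
hypertension is split across two endpoints — the achieved blood pressure and
the number of antihypertensive drugs needed to hold it — and measuring
either alone understates benefit. `htindex` implements the **Hypertensive
Index (HTi)**, a composite score of excess systolic pressure and medication
load:

```
HTi = (SBP − 120) × (n_meds + 1)
```

where SBP is systolic blood pressure in mmHg and `n_meds` the count of
prescribed antihypertensive agents. An SBP of exactly 120 scores 0 whatever
the drug count; pressures below 120 score negative (a possible marker of
over-treatment). The package is aimed at clinical researchers analysing
paired baseline/discharge cohorts from hypertension interventions (renal
artery stenting, denervation, and similar), and provides:

* the index, its diastolic / mean-arterial / pulse-pressure variants, and
  the flat "+10 mmHg if treated" comparator score (`hti()`, `gwas_score()`);
* the four-group treatment-response classification (BP↓/↔ × drugs↓/not) and
  the successful-intervention label (`classify_cohort()`, `is_success()`);
* rank-based ROC comparison of improvement scores against the success label
  (`roc_curve()`, `compare_predictors()`), with ties credited one half;
* a seeded synthetic cohort generator calibrated to the published group
  moments of a 99-patient renovascular-intervention cohort
  (`generate_cohort()`), so the whole pipeline runs without patient data;
* validated cohort CSV input/output and summary-table reporting with a
  normality-gated test-selection policy (`read_cohort()`, `summary_table()`,
  `group_summary()`, `paired_comparison()`).

## Worked example

```r
library(htindex)

hti(c(145, 130, 120, 110), c(2, 4, 7, 0))
#> [1]  75  50   0 -10
```

A pressure of 145 mmHg on two drugs scores 75, while 130 mmHg bought with
four drugs scores 50 — better overall control despite more tablets. On a
full (here synthetic) cohort:

```r
coh <- generate_cohort(seed = 1)   # 99 patients, groups 46/29/15/9
fit <- hti_analysis(coh)
fit
#> Hypertensive Index cohort analysis (99 patients)
#>   response groups 1-4: 46 / 29 / 15 / 9  (85% successful)
#>   top improvement score by AUC: d_gwas (0.973)

summary(fit)
#> Baseline vs discharge (whole cohort):
#>  variable  n baseline_center discharge_center ... p_value                 test_name
#>       sbp 99          187.62           137.83 ... 3.985e-17 Wilcoxon signed-rank test
#>       dbp 99           90.94            77.13 ... 1.052e-17             paired t-test
#>      meds 99            4.00             2.00 ... 7.335e-12 Wilcoxon signed-rank test
#>       hti 99          305.59            56.04 ... 7.383e-18 Wilcoxon signed-rank test
#>
#> ROC comparison of improvement scores:
#>  predictor    auc n_pos n_neg
#>     d_gwas 0.9730    84    15
#>      d_sbp 0.9635    84    15
#>      d_hti 0.9595    84    15
#>      d_dbp 0.9000    84    15
#>     d_meds 0.5865    84    15
#>
#> Spearman rho (baseline index vs improvement): 0.89 (n = 99)
```

Every variable falls sharply after intervention; the index improvement
detects success far better than medication load alone (AUC 0.96 vs 0.59 on
this cohort), and patients with the highest baseline index gain the most
(Spearman ρ = 0.89). See the methods vignette
(`vignettes/hypertensive-index.Rmd`) for the model, the generator's
assumptions, and why the synthetic cohorts overstate the systolic-pressure
comparators.

External trials can be scored from their published summary tables:

```r
hti_from_summary(150, 2.1)   # CORAL trial at entry: mean SBP 150 on 2.1 drugs
#> [1] 93
```

A thin command-line front end over the same functions is installed at
`inst/cli/hti.R` (`simulate`, `score`, `classify`, `roc`, `report`
subcommands sharing the cohort CSV schema).

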