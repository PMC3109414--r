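# csfchange

Change-point analysis of cross-sectional relations between cerebrospinal-fluid
(CSF) biomarkers and cognitive scores.

## The problem

In Alzheimer's disease, CSF levels of amyloid peptides (Aβ1-40, Aβ1-42) and
Tau proteins (total Tau, phospho-Tau-181) differ between demented and
non-demented people. The question this package addresses is *how* those
levels relate to a global cognitive score — the CAMCOG total, an integer 0-107
with higher scores meaning better cognition — across the whole range from
health to dementia. A linear relation would mean the biomarkers keep tracking
severity; a **change-point** structure means the relation changes regime at
some score, typically near the lower edge of the normal range, and is weak or
absent below it — implying most biomarker change precedes clinical dementia.

For a biomarker level *y* and score *c*, the working model is a broken stick
with a change-point θ,

    E[y | c] = μ_θ + β_above (c − θ) 1[c > θ] + β_below (c − θ) 1[c ≤ θ],

with side-specific residual variances, and the analysis asks (i) where the
level and the slope of the relation change, (ii) whether a two-regime fit
beats a single line (nested F on 2, n−4 df), and (iii) whether medians,
variances, Spearman ρ and robust (MM-estimation) slopes differ between the
sides of the change-point.

The package is aimed at biostatisticians and dementia researchers who want
these analyses as tested, reusable building blocks:

* `synthetic cohort` — `default_scenarios()`, `generate_cohort()`: cohorts
  with the published statistical structure (bimodal CAMCOG mixture,
  piecewise-linear heteroscedastic biomarkers, optional contamination) as
  ground-truth test beds, since the original cohort data are not deposited.
* `robust statistics` — `mm_regression()` (S-stage breakdown 0.5, M-stage 95%
  efficiency), `lowess_fit()`, `spearman_rho()`, `mann_whitney()` (exact by
  dynamic programming up to a cap), `variance_ratio_test()`,
  `categorical_tests()`.
* `level change-points` — `fstat_scan()` (structural-change F scan with
  permutation p), `rss_breakpoint()`, `chow_f()`.
* `slope change-points` — `tie_split_ranks()`, `segment_series()`
  (bottom-up piecewise-linear segmentation with a tolerance angle),
  `escalate_until_single()`, `slope_changepoint()` (the 1000-repetition
  tie-splitting resampler; median of the per-repetition estimates).
* `inflection MANOVA` — `design_with_inflection()`, `manova_term_test()`
  (Wilks Λ, exact F for single-df terms), `inflection_manova()`.
* `orchestration` — `run_biomarker()`, `combine_changepoints()`,
  `side_statistics()`, `segmented_vs_linear()`, `summary_table()`,
  `demographics_table()`, `plot_biomarker_fit()`.

The numbered scripts under `analysis/` run the whole sequence and write
tables to `results/`.

## Worked example

```r
library(csfchange)

cfgs <- default_scenarios()          # change-points at CAMCOG 90, 90, 94, 93
tab  <- generate_cohort(cfgs, n_control = 95, n_ad = 97, seed = 1)

demographics_table(tab)$summary
#>         group   gender             age         mmse         camcog
#>  non-demented 56F: 39M 72.3 (69-78.95) 27 (23.5-29) 100 (80.5-105)
#>            AD 55F: 42M  73.4 (67-78.8)    17 (5-28)    64 (18-100)

inflection_manova(tab, inflect_at = 89)$slopes
#> MANOVA term 'hinge': Wilks lambda = 0.8223, F = 9.779 on 4/181 df, p = 3.487e-07 (n = 192)
```

The omnibus test says the four biomarkers jointly change slope near CAMCOG
89 (the level-shift term is null here — the generator's means are continuous,
so only the slope carries signal). Per biomarker, the two change-point
analyses and their combination:

```r
scan <- fstat_scan(tab$camcog, tab$abeta42, n_perm = 500, seed = 1)
bp   <- rss_breakpoint(tab$camcog, tab$abeta42)
slo  <- slope_changepoint(tab$camcog, tab$abeta42, repetitions = 1000,
                          master_seed = 1)
combine_changepoints(bp$camcog, slo$median)$combined
#> [1] 98
scan
#> Structural-change scan (linear model, n = 192, trim 0.15): sup F = 11.729 at CAMCOG 96, permutation p = 0.002
```

For this draw the Aβ1-42 change-point lands at CAMCOG 98 against a
configured 90: single-cohort estimates scatter by several points at these
noise levels (the methods vignette quantifies this), which is why the
recovery analyses below always aggregate over replicate cohorts.

```r
res <- run_biomarker(tab, "abeta42", repetitions = 200, seed = 1)
res$model_comparison$f; res$model_comparison$p_value
#> [1] 7.717166
#> [1] 0.0006011165   # the two-regime fit beats the single line
res$figure                # four-model overlay (means, robust line,
                          # two-regime fit, lowess)
```

`summary_table(list(res, ...))` renders the side-specific medians,
variances, Spearman ρ and robust slopes in the classic wide Above/Below
layout with two-level significance stars.

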