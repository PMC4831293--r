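# paritymeta

Meta-analysis of summarized epidemiological study reports on **parity**
(number of live births) and **thyroid cancer risk** in women.

Observational studies of this association print, per study, a ladder of
parity categories with a relative risk (RR, OR, or HR — treated as
interchangeable for a rare outcome) and a 95% confidence interval against a
nulliparous reference group. `paritymeta` turns those printed numbers into a
complete, reproducible analysis pipeline for epidemiologists and
meta-analysts:

* **Effect extraction.** Each printed pair becomes a log effect
  `y = log(RR)` with standard error
  `se = (log(UCL) − log(LCL)) / (2 × 1.959964)`.
* **Pooling.** Fixed-effects inverse-variance pooling
  (`ŷ = Σ wᵢyᵢ / Σ wᵢ`, `wᵢ = 1/seᵢ²`) and DerSimonian–Laird
  random-effects pooling
  (`τ̂² = max(0, (Q − df) / (Σw − Σw²/Σw))`, re-weight by
  `1/(seᵢ² + τ̂²)`), with Cochran's `Q`, `I² = max(0, (Q − df)/Q) × 100`,
  and the conventional switch to the random model when `I² > 50%`.
* **Subgroups and sensitivity.** Stratified pooling by design, quality
  (Newcastle–Ottawa ≥ 7 = high), region, control type and confounder
  adjustment; leave-one-out re-pooling.
* **Publication bias.** Egger's precision regression (intercept t-test with
  k − 2 df) and the Begg–Mazumdar rank correlation (tie-corrected,
  continuity-corrected Kendall statistic; exact permutation p for k ≤ 8).
* **Dose–response.** Category doses by the midpoint rule (open-ended top
  categories take the width of the adjacent interval); per-study GLS trends
  through the origin under an `independent`, `gl_counts`
  (Greenland–Longnecker) or `hamling` pseudo-count covariance for the
  shared-reference correlation; two-stage pooling of slopes; restricted
  cubic splines with three knots at the 10/50/90th percentiles of the dose
  distribution; likelihood-ratio and Wald tests of nonlinearity.
* **Synthetic literatures.** `simulate_catalog()` generates catalogs with
  known truth (design mix, true dose–response curve, between-study τ²,
  optional one-sided publication selection) so every estimator's
  calibration is testable.

The package ships a transcribed catalog of 24 published study reports
(23 studies; one study reports women under and over 45 separately) in
`inst/extdata/parity_thyroid_catalog.csv`.

## Worked example

```r
library(paritymeta)

cat24 <- parity_catalog()
pool  <- meta_pool(contrast_effects(cat24, "parous"), method = "fixed")
pool
#> Pooled RR (fixed-effects, k = 24): 1.100 (95% CI 1.038-1.165)
#> Heterogeneity: Q = 47.744 (df = 23, p = 0.002), I2 = 51.8%, tau2 = 0.0000
```

Parous women show a pooled relative risk of about 1.10 against nulliparous
women, with moderate between-study heterogeneity. The single-parity
contrasts restrict to reports printing that exact category:

```r
meta_pool(contrast_effects(cat24, "parity2"), method = "fixed")
#> Pooled RR (fixed-effects, k = 12): 1.112 (95% CI 1.012-1.222)
#> Heterogeneity: Q = 15.970 (df = 11, p = 0.142), I2 = 31.1%, tau2 = 0.0000
```

Dose–response, with doses assigned by the midpoint/open-interval rules:

```r
dose_trend(cat24)
#> Dose-response trend over 22 reports (independent covariance)
#>   RR per live birth: 1.037 (95% CI 1.001-1.075), p = 0.043 (random-effects)
#>   Heterogeneity of slopes: I2 = 69.5%, p = 5.3e-07
#>   Spline (knots 1.00/2.75/5.50, k = 22): LR = 0.279, p-nonlinear = 0.598
```

The per-birth trend is close to null and there is no evidence of
nonlinearity. `run_full_report(cat24, outdir = "out")` runs every stage in
one pass and writes plot-ready TSV tables plus a JSON manifest.

## Input format

One CSV row per exposure category, report metadata repeated per row:

```
report_id, author_year, design, design_detail, region, nos_score, adjusted,
total_cases, total_subjects, category_label, lower, upper, is_reference,
rr, lcl, ucl, n_cases, n_denominator
```

`design` is `prospective` or `case_control`; `design_detail` one of
`cohort`, `nested_cc`, `case_cohort`, `population_cc`, `hospital_cc`,
`pooled_cc`. Parity ranges are closed integer intervals; an empty `upper`
marks an open-ended category ("≥3"); a row labelled `Parous` is a study's
own all-parous contrast. `n_cases`/`n_denominator` (per-category counts)
may be empty; they enable the `gl_counts` covariance.

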