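---
title: "Methods: meta-analysis of parity and thyroid cancer risk from printed study tables"
author: "paritymeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meta-analysis of parity and thyroid cancer risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paritymeta)
```

## The problem

Whether bearing children changes a woman's risk of thyroid cancer has been
studied in dozens of case-control and cohort studies, with inconsistent
answers. None of those studies deposited individual-level data; what
survives of each is a printed table: a nulliparous reference category and a
ladder of parity categories, each with a relative risk (or odds/hazard
ratio, treated as equivalent for a rare outcome) and a 95% confidence
interval, sometimes accompanied by a single "parous" summary contrast.
`paritymeta` is a complete pipeline for analysing such summarized evidence:
effect extraction, fixed- and random-effects pooling, heterogeneity,
subgroup and leave-one-out sensitivity analyses, funnel-plot asymmetry
tests, and categorical dose-response modelling. It ships a transcribed
catalog of 24 such study reports (23 studies; one reports two age strata
that are treated as separate reports because no combined estimate can be
formed from the printed numbers).

## Effect extraction

Every printed `RR (LCL–UCL)` row becomes a log effect
$y = \log RR$, $se = (\log UCL - \log LCL) / (2 \times 1.959964)$,
assuming the interval was computed on the log scale. We use the full
normal quantile 1.959964 rather than 1.96; the difference is far below the
rounding of the printed inputs, but it makes the interval arithmetic
self-consistent (simulated Woolf intervals invert exactly).

Printed values are taken at face precision. A consequence worth knowing:
the printed point estimate need not be the geometric mean of its printed
bounds (a row like "0.9 (0.3–2.3)" is ~8% off log-symmetry), so intervals
recomputed from $(y, se)$ preserve the printed interval's *ratio* exactly
but can drift from the printed *bounds* by the rounding of the point
estimate. This bounds the fidelity of any reconstruction from printed
tables.

## The parous-vs-nulliparous contrast and the category-collapse problem

Sixteen of the 24 reports print their own "Parous" row, which is used as
is. The other eight print only per-category estimates, which must be
collapsed into a single parous-vs-nulliparous contrast. Two collapses are
implemented behind `combine_categories()`:

* `iv` (default): fixed-effects inverse-variance combination of the
  category log effects. This ignores the correlation induced by the shared
  nulliparous reference group, which overstates the precision of the
  collapsed contrast; it is, however, the transparent and standard naive
  choice.
* `hamling`: reconstruct pseudo-counts for every category (see below),
  aggregate the parous cells, and recompute the contrast with its Woolf
  variance from the aggregated table. This respects the shared-reference
  correlation at the cost of a nonlinear reconstruction.

The choice is isolated behind one argument precisely because it is the
least identified step of the whole pipeline: published analyses of this
literature rarely state how they formed the contrast, and stratified
heterogeneity statistics turn out to be quite sensitive to it. On the
packaged catalog the overall pooled RR moves only between 1.09 and 1.11
across collapses, but stratum-level I² values move by tens of percentage
points. No collapse rule we examined (inverse-variance, pseudo-count,
single-category variants) reproduces every published stratum of this
literature simultaneously, which we take as evidence that reconstruction
from the printed table alone cannot recover the original authors' exact
per-report contrasts; the package reports what its stated, documented rule
produces.

## Pooling and heterogeneity

Fixed-effects pooling is inverse-variance: $\hat y = \sum w_i y_i / \sum
w_i$, $w_i = 1/se_i^2$, $se(\hat y) = (\sum w_i)^{-1/2}$. Heterogeneity is
summarized by Cochran's $Q = \sum w_i (y_i - \hat y)^2$ on $k-1$ degrees
of freedom (upper-tail chi-square p, no small-k correction; $p = 1$ at
$k = 1$) and $I^2 = \max(0, (Q - df)/Q) \times 100$ (defined as 0 when
$Q = 0$). Random-effects pooling is DerSimonian-Laird:
$\hat\tau^2 = \max(0, (Q - df)/(\sum w - \sum w^2/\sum w))$, then
re-weight by $1/(se_i^2 + \hat\tau^2)$.

`meta_pool(method = "auto")` applies the conventional switch: random
effects if and only if the fixed-effects $I^2$ exceeds 50%. The switch is
applied *per analysis* (each stratum, each leave-one-out fit) — the rule's
granularity is otherwise ambiguous, and per-analysis is the only
self-consistent reading. The reported $I^2$ is always the fixed-effects
one, matching the universal reporting convention. Note that `auto` is a
data-dependent model choice; the acceptance script pools the headline
contrasts with `method = "fixed"`, which is how this literature's summary
estimates are conventionally reported when $I^2 < 50\%$.

## Publication bias

`egger_test()` regresses the standardized effect $y_i/se_i$ on precision
$1/se_i$ by OLS; the intercept estimates funnel asymmetry and is tested
two-sided against $t_{k-2}$. `begg_test()` standardizes against the
fixed-effects pooled value, $y_i^* = (y_i - \hat y_{FE}) / \sqrt{se_i^2 -
se_{FE}^2}$, and computes Kendall's score between $y^*$ and the variances,
with the tie-corrected null variance and the continuity correction
(|score| reduced by 1) used by the long-standing Stata implementation; an
exact permutation p is available for $k \le 8$. Both tests are invariant
to multiplying every RR by a constant.

## Dose assignment

The reference category anchors dose 0. A category $[k,k]$ gets dose $k$; a
bounded range $[a,b]$ its midpoint; an open-ended top category $[a,+)$ is
treated as an interval of the same width $w$ as the adjacent (next-lower)
bounded category, hence dose $a + w/2$. Two edge cases the midpoint rule
does not anticipate are resolved as: if the adjacent category is a single
value (width 0), and for a lone open-ended category with no bounded
neighbor at all, the width defaults to one live birth (the natural unit of
this exposure; the latter case also warns). Reports that print only a
"Parous" summary row have no category ladder and drop out of dose-response
estimation — on the packaged catalog, 22 of 24 reports contribute.

## Within-study trends and the shared-reference covariance

Because all categories of a report share its reference group, their log
effects are positively correlated. `reconstruct_covariance()` offers:

* `independent` — diagonal of printed variances. The default, because the
  packaged catalog prints no per-category counts, and the default should
  not depend on a reconstruction that printed data cannot pin down.
* `gl_counts` — Greenland-Longnecker-type fitted table: case counts
  consistent with the printed (adjusted) RRs and the crude margins
  (per-category denominators plus total cases, available in synthetic and
  some real catalogs); covariance from the fitted reference cells, rescaled
  to the printed variances so each contrast keeps its adjusted precision.
* `hamling` — pseudo-counts matching each RR *and* its CI, with reference
  cells chosen so the implied totals match the report's case/non-case
  margins. The margin system can admit two nearby solutions; the solver
  (a nested one-dimensional root search) then returns the one with the
  larger reference cells, i.e. the weakest implied correlation — the
  conservative choice closest to independence. Margins that are
  incompatible with the printed precision (covariate adjustment, rounding)
  yield the closest achievable table, flagged `converged = FALSE`.

Each report's linear trend is generalized least squares of the
non-reference log effects on dose *through the origin* (the reference
pins $\log RR = 0$ at dose 0): $\hat\beta = (x^\top C^{-1}x)^{-1}
x^\top C^{-1} y$. Slopes are pooled across reports with `meta_pool`
(two-stage estimation); the per-birth RR is $\exp(\hat\beta_{pooled})$
with a normal test for the linear trend.

## Splines and the nonlinearity test

The nonlinear model uses a restricted cubic spline with three knots at the
10/50/90th percentiles (linear interpolation between order statistics) of
the pooled, unweighted multiset of assigned non-reference doses — the dose
"distribution" available to a summarized-data analysis. With three knots
the spline adds exactly one nonlinear term (Harrell normalization),
`rcs_basis()`, zero below the first knot and linear beyond the last.

Spline coefficients are pooled by fixed-effects multivariate inverse
variance over the reports that can identify both coefficients (at least
two non-reference categories and a full-rank basis); for a fixed-effects
two-stage fit this is algebraically the one-stage GLS solution, so the
difference in generalized residual sums of squares between the nested
linear and spline fits — both estimated on the spline-eligible reports —
is a proper likelihood-ratio-type statistic, non-negative by construction
and referred to $\chi^2_1$. The Wald test on the pooled nonlinear
coefficient is reported as a cross-check; the two agree closely in
practice. A catalog with fewer than three distinct doses (or fewer than
two spline-eligible reports) cannot identify the spline; the linear trend
is then reported alone.

## The synthetic-data generator

`simulate_catalog()` emulates the structure of this literature so every
estimator can be validated against known truth. Its defaults mirror the
packaged catalog: 24 reports, a 14:10 case-control:cohort mix, expected
case counts spanning 50–1500 (the real reports span 29–2247), a
nulliparous reference plus a 1 / 2 / ≥3 ladder, and a modest between-study
variance of $\tau^2 = 0.02$ on the log-RR scale (the heterogeneity range
suggested by the real catalog's $I^2$). Case-control reports draw exposure
multinomially for cases (probabilities tilted by the true category odds
ratios) and an equal number of controls; cohort reports draw Poisson
counts against per-category person-time with baseline incidence $10^{-4}$
per person-year — the order of magnitude of female thyroid-cancer
incidence. Intervals are Woolf (log-normal) intervals from the realized
counts, so effect extraction inverts them exactly; counts are retained so
the `gl_counts` covariance is exercised end to end. Optional one-sided
selection suppresses studies whose parous contrast is not significantly
positive with a configured probability.

What the generator does *not* emulate: covariate adjustment (simulated RRs
are crude), printed rounding, matched designs, and reporting quirks such
as parous-only rows. Passing calibration tests on synthetic catalogs
therefore demonstrates the estimators' correctness under the stated
sampling models, not robustness to every idiosyncrasy of real tables.

All randomness flows from one integer seed in the configuration;
regenerating with the same configuration is bit-identical.

## Numerical and design choices

* Zero-width or inverted printed intervals are rejected, not repaired.
* $Q = 0$ defines $I^2 = 0$ (avoiding 0/0); DL truncates $\hat\tau^2$ at 0.
* Reconstructed correlations are clamped to $[0, 0.95]$ before rescaling,
  keeping every covariance matrix positive definite.
* Simulated zero cells are resampled a bounded number of times, then the
  study size is inflated with a message; nothing is silently dropped.
* Single-report strata pool to themselves ($Q = 0$, $p = 1$); empty strata
  are omitted rather than erroring.
* Matched-only designs count as confounder-adjusted (matching is an
  adjustment); a pooled re-analysis of several case-control studies is one
  report, carries no quality score, and belongs to neither control-type
  stratum.
* Monte-Carlo validation sizes (1000–2000 replicates for calibration, a
  few hundred for distributional checks) were chosen to make binomial /
  Kolmogorov-Smirnov error bands decisively smaller than the effects being
  checked.

## Known limitations

* The collapse of category-only reports to a parous contrast is not
  identifiable from printed data (above); stratum-level heterogeneity
  statistics inherit that uncertainty.
* Pseudo-count reconstructions treat printed margins as exact; covariate
  adjustment makes them only approximately compatible, and the Hamling
  margin system is occasionally bistable or infeasible (then flagged).
* The dose-response stage assigns a single dose per category; wide or
  open-ended top categories are represented by one point, a known
  limitation of aggregate dose-response analysis.
* No Hartung-Knapp adjustment, meta-regression, prediction intervals, or
  trim-and-fill; these are outside the pipeline's scope.
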