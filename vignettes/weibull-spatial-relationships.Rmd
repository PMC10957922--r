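---
title: "Threshold-free spatial relationships from 1-NN distance distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-free spatial relationships from 1-NN distance distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multiplex immunofluorescence (mIF) reduces a tissue slide to a point map:
one nucleus-centroid coordinate and one phenotype per cell, here a closed
7-class vocabulary (cancer, CD8+ T, FoxP3+ T, T-helper, B cell, macrophage,
and "negative" — cells negative for every panel antibody). The standard
summaries of such maps are compartment densities, which ignore exactly the
thing that matters for many immune interactions: proximity. `weibullSR`
models the spatial relationship (SR) of an ordered cell-type pair through
the distribution of first-nearest-neighbor (1-NN) distances — for every
reference cell of type *from*, the Euclidean distance to its closest cell of
type *to* — and summarizes that distribution with the two parameters of a
Weibull density fitted jointly across a cohort.

The Weibull model

$$f(x; a, b) = \frac{a}{b}\left(\frac{x}{b}\right)^{a-1}
  e^{-(x/b)^a}, \qquad x \ge 0,$$

is a natural family here: under complete spatial randomness (CSR) of the
target type with intensity $\lambda$, cross 1-NN distances are exactly
Weibull with shape $a = 2$ and scale $b = (\pi\lambda)^{-1/2}$, and departures
from CSR move the pair through interpretable regimes (densely packed targets:
low scale/high shape; co-mingled clusters: low scale/low shape; sparse
dispersed targets: high scale/low shape; mutually displaced clusters: high
scale/high shape). Unlike G-function summaries (G-AUC-T), no distance
threshold has to be chosen.

## The estimation pipeline

1. **1-NN distances** (`cross_nn_distances`). Exact nearest neighbors on the
   whole slide (no compartment stratification), asymmetric in the pair
   ordering; for self-self relationships a cell is excluded as its own
   neighbor. Ties in distance are interchangeable. The implementation is a
   chunked exact search; a brute-force all-pairs oracle backs it in the
   tests.
2. **Smoothed density** (`smooth_nn_pdf`). A 5-µm window slides across the
   1-NN histogram at 1-µm steps; the window is half-open
   $[t - 2.5, t + 2.5)$, so each distance supports exactly five grid points.
   The curve is normalized to unit trapezoidal area.
3. **Cohort fit** (`fit_weibull_nlme`). The smoothed curves of all samples
   are fitted jointly as
   $\text{density}(t) \approx f(t; a_i, b_i) + \varepsilon$, a nonlinear
   mixed-effects model (REML, via `nlme`) in the unconstrained coordinates
   $a_i = 10/(1 + e^{-A_i})$, $b_i = 500/(1 + e^{-B_i})$, with population
   fixed effects $(A, B)$ and per-sample Gaussian random effects with
   diagonal covariance. Reported per-sample parameters are fixed effect +
   predicted random effect, mapped through the links. Initialization comes
   from per-sample maximum-likelihood estimates on the raw distances
   (`fitdistrplus::fitdist`), with a curve-moment fallback.
4. **Derived quantities**. The analytic CDF $1 - e^{-(r/b)^a}$, its AUC up
   to a threshold (Weibull-G-AUC-T), and the median 1-NN distance
   $b(\ln 2)^{1/a}$.

### Numerical choices that matter

* **Fitting grid.** Curves enter the fit on the integer grid restricted to
  (0, 99th percentile of the pooled distances]. The $t = 0$ bin is excluded
  for two reasons: the Weibull density is unbounded at 0 whenever a sample's
  shape drops below 1, which destabilizes the penalized least-squares step,
  and the half-open window makes the 0-bin boundary-biased (it only sees
  half a window).
* **Smoothing bias.** The 5-µm window inflates the spread of the fitted
  distribution. For CSR at $\lambda = 0.005\,\mu m^{-2}$ the infinite-data
  fit of the smoothed curve gives $b \approx 8.25$ µm against the exact
  7.979 µm (about +3.5%) and $a \approx 1.96$; this is a property of the
  stated construction, not an estimation error, and is stable across
  cohorts.
* **Link bounds.** Shapes and scales live in (0, 10) and (0, 500) µm.
  Distance sets whose true scale approaches 500 µm (or whose concentration
  pushes the shape toward 10) sit near the link saturation, where fits slow
  down or fail; such relationships are exactly the ones the filter ladder
  and the rejection path are for.
* **Convergence and bounded compute.** An optimization attempt (primary
  optimizer `nlm` with the control constants maxIter = 1000,
  msMaxIter = 200, pnlsTol = 0.1, tolerance = 1e-6, then one `nlminb`
  fallback) is also bounded by a 30-s wall clock (`max_fit_seconds`); a
  timeout counts as non-convergence. Refits on an unchanged sample set are
  skipped, since they cannot differ.
* **Filter ladder** (`sequential_filter_fit`). On non-convergence, samples
  with fewer than 20 reference or target cells are dropped and the fit
  retried, then at 50, 70 and 100 cells; a relationship that still fails is
  *rejected* — a first-class outcome, not an error. This mirrors the
  observation that low-count distance sets are the typical cause of
  non-convergence.

## Segmentation, metrics and the association battery

Foci are split by DBSCAN (epsilon 300 µm, minimum 50 points; noise cells get
focus id −1). Per focus, Gaussian-kernel intensity surfaces of cancer and of
negative cells are max-normalized and compared at each cell position
(bilinear interpolation): cancer surface strictly greater means tumor,
otherwise stroma — so exact ties and cancer-free foci are stroma, and
negative-free foci are tumor. Bandwidths are selected by likelihood
cross-validation (leave-one-out point-process log-likelihood over 16
log-spaced candidates between 2 µm and a quarter of the window diagonal;
Scott's rule when the profile is monotone). The pixel grid defaults to 10 µm
and at least 64×64 per focus; areas count pixels whose normalized intensity
reaches 0.1 (tumor from the cancer surface, total tissue from the
renormalized sum of both surfaces, stroma as the difference). An optional
150-µm trim drops stroma cells whose nearest cancer cell is farther than
150 µm, aligning tumor purity across differently sampled cohorts.

Densities are counts per compartment area (cells/mm²); the exclusion ratio
(stromal over intratumoral density) adds a 0.5-cell continuity correction to
both counts so it stays finite and log-transformable — raw densities are
reported uncorrected. Group comparisons use a two-sided Welch t-test (the
common software default for a "t-test"; the pooled-variance variant is a
switch) on the declared analysis scale — natural log for densities,
exclusion ratios and the Weibull scale, linear for the shape — with
Benjamini–Hochberg adjustment within each metric family (all SR shapes are
one family, all SR scales another, densities and exclusions their own) and
significance at FDR < 0.10. Fold changes are differences of group means on
the analysis scale. Median-distance comparisons use the exact Mann–Whitney
test (normal approximation above 20 per group). Prediction uses unpenalized
logistic regression with the ROC built from in-sample fitted probabilities —
deliberately optimistic, reported as such — the rank-statistic AUC,
percentile bootstrap CIs (500 class-stratified replicates), paired one-sided
bootstrap AUC comparisons, and leave-one-out residual-deviance comparisons
between feature sets.

## What the synthetic cohorts emulate — and what they do not

`simulate_tme_cohort` builds slides with cancer cells in Thomas-process
nests (Poisson parents, Gaussian offspring — chosen for its closed-form
intensity and standard usage), a CSR negative-cell stroma, and rarer immune
populations whose proximity to cancer differs by response group: responders
place immune cells by Gaussian offsets (SD 5 µm) around random cancer cells,
non-responders by thinning uniform candidates with a Gaussian kernel on the
nearest-cancer distance centered at 22 µm. With the defaults (24 samples,
14 responders / 10 non-responders, 1000×1000 µm windows, ~750 cancer and
~800 negative cells and 30–80 cells per immune type per slide) the median
CD8→cancer 1-NN distance comes out near 4 µm in responders and near 18 µm in
non-responders — the magnitude of the group gap the method is meant to
detect — without claiming to reproduce any cohort-level statistic.
`simulate_weibull_cohort` draws per-sample $(A_i, B_i)$ from the generating
Gaussian random-effect model and distances from the implied Weibulls: the
oracle for parameter recovery. Scenario presets (`simulate_sr_scenario`)
cover the four scale/shape regimes, with lognormal (SD 0.25) between-sample
abundance jitter — without it, a cohort of identically distributed samples
has exactly zero random-effect variance, which is a degenerate corner for
any mixed model.

What passing these tests does **not** show: real slides have irregular
tissue boundaries, holes, segmentation-driven phenotype errors, spatially
varying cell density within a compartment, and patient-level covariance
between cell types. None of that is emulated; the synthetic cohorts validate
the estimator and the pipeline plumbing, not the biology.

## Problem sizes and calibration, as measured here

The validation battery in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R` uses 24-sample cohorts (about 300 reference and 5000
target cells per slide for the CSR check; 2000 distances per sample for
recovery), 20 replicate cohorts for coverage, and 8-sample preset cohorts
for the scenario taxonomy. Over repeated simulated cohorts the 2-SE
intervals of the two population fixed effects cover their generating values
at roughly their nominal 95% rate (shape-link slightly above, scale-link at
it), so recovery is assessed per fixed effect. The CSR check recovers shape
within [1.85, 2.15] and scale within 5% of $(\pi\lambda)^{-1/2}$, the scale
margin being dominated by the ~3.5% smoothing bias discussed above.

## Known limitations

* Only the first nearest neighbor is modeled; k-NN, Ripley-type and
  graph statistics are out of scope by design.
* The empirical G estimator is the raw ECDF by default; a reduced-sample
  border-corrected variant is available but the primary results do not use
  edge correction.
* In-sample ROCs overstate external performance; no cross-validated ROC is
  offered.
* Fits near the link bounds (scale ≳ 450 µm at desk-scale windows) are
  unreliable and typically end as rejections; widening the bounds would
  change the model, not fix the geometry.
* The likelihood cross-validation for bandwidths treats the integrated
  intensity as constant across candidates (exact up to edge effects).
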