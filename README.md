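# weibullSR

Threshold-free quantification of spatial relationships (SRs) in multiplex
immunofluorescence (mIF) cell maps.

An mIF experiment reduces a tumor slide to per-cell coordinates (µm) and
phenotypes — here cancer cells, CD8+ T cells, FoxP3+ T cells, T-helper
cells, B cells, macrophages, and "negative" cells (negative for every panel
antibody). Density summaries of such maps discard proximity, which is the
physical prerequisite of most immune interactions. `weibullSR` instead
summarizes the SR of each ordered cell-type pair by the distribution of
first-nearest-neighbor (1-NN) distances — from every *reference* cell, the
distance to the closest *target* cell — and fits that distribution with a
Weibull density

  f(x; a, b) = (a/b) (x/b)^(a−1) exp(−(x/b)^a),

whose shape *a* and scale *b* describe the SR without any distance
threshold. The fit is a nonlinear mixed-effects model across the cohort:
the smoothed (5-µm window, unit-area) per-sample 1-NN density curves are
fitted jointly with population fixed effects and per-sample random effects
on the logistically re-parameterized coordinates a = 10/(1+e^−A),
b = 500/(1+e^−B), by REML. Under complete spatial randomness of the target
type with intensity λ, the 1-NN distribution is exactly Weibull with a = 2
and b = (πλ)^−1/2, which anchors the validation suite.

The package also provides the supporting machinery of a full SR analysis:

* tissue-focus splitting (DBSCAN, eps 300 µm / 50 points) and tumor/stroma
  segmentation by comparing max-normalized kernel intensity surfaces of
  cancer vs. negative cells, compartment areas, and a 150-µm distal-stroma
  trim;
* empirical G-functions (the 1-NN CDF) and their threshold summaries
  G-AUC-T, plus the analytic Weibull-derived CDF, G-AUC and median
  b (ln 2)^(1/a);
* a sequential cell-count filter ladder (20/50/70/100 cells) that drops
  low-count samples only when the cohort fit fails, and a first-class
  *rejected* outcome when it keeps failing;
* compartment densities (cells/mm²), stromal/intratumoral exclusion ratios,
  differential tests with Benjamini–Hochberg FDR by metric family,
  Mann–Whitney median-distance comparisons, logistic-regression ROC with
  bootstrap CIs and paired one-sided ROC comparisons, leave-one-out
  deviance comparisons;
* seed-reproducible synthetic cohorts (Thomas-process tumor nests with
  response-dependent immune proximity, CSR oracles, Weibull random-effect
  cohorts, four scale/shape scenario presets) so everything is testable
  without patient data;
* a one-command pipeline (`run_full_pipeline()`) that enumerates every
  (sample × ordered pair) fitting unit, isolates per-unit errors, and
  writes metrics, fit reports and a checksummed JSON manifest, plus a thin
  CLI at `inst/cli/weibullsr`.

## Worked example

```r
library(weibullSR)

cohort <- simulate_tme_cohort(
  sim_config(n_responders = 4, n_non_responders = 3, seed = 42))

sets <- lapply(split(seq_len(nrow(cohort$cells)), cohort$cells$sample_id),
               function(i) cross_nn_distances(cohort$cells[i, ],
                                              "cd8_t", "cancer"))
fit <- sequential_filter_fit(sets)
print(fit)
#> Weibull SR fit [cd8_t->cancer]: shape = 2.168, scale = 10.370 um (filter level none, 7 samples)
#>   random-effect SDs: A 0.229, B 0.686; residual sigma 0.007212

mt <- median_distance_test(fit, cohort$labels)
#> median 1-NN distance: responders 4.8 um, non-responders 19.6 um
#> (Mann-Whitney p = 0.057)
```

The cohort-level shape ≈ 2.2 and scale ≈ 10 µm describe the pooled
CD8→cancer relationship; the per-sample scale random effect (SD 0.69 on the
link scale) carries the biology — responder immune cells sit a median
~5 µm from their nearest cancer cell, non-responders ~20 µm, and the
per-sample Weibull medians make that difference testable despite only seven
samples.

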