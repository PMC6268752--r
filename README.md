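# sdarforest

Binary classifiers of cytochrome P450 (CYP3A4 / CYP2D6)
inhibitor vs non-inhibitor status from two complementary descriptor
families, for cheminformatics and drug–drug-interaction screening work:

* **SDAR** — the *spectral data–activity relationship* route. A compound's
  predicted ¹³C and ¹⁵N NMR chemical shifts are binned into occupancy
  counts (schemes C1&N5, C2&N10, C3&N15: 1/2/3 ppm carbon with 5/10/15 ppm
  nitrogen bins) and classified by two-class linear discriminant analysis
  with forward stepwise bin selection. Selection is driven by the Wilks'
  lambda partial F,

  F = (n − 2 − p) (Λ_S / Λ_{S∪v} − 1),   Λ_S = det W_S / det T_S,

  with entry/removal thresholds F > 0.5 or F > 2.0 and equal priors
  (π₀ = π₁ = ½) to counter class imbalance.

* **SAR** — the structural route. A numeric molecular-descriptor table is
  reduced by a Shannon-entropy filter (H = −Σ pᵢ log₂ pᵢ over an
  equal-width histogram; low-information columns dropped) and classified by
  a **decision forest**: an ordered consensus of five Gini-split decision
  trees built on mutually disjoint descriptor subsets (6–17 distinct
  descriptors per tree), predicting by the mean of the trees' leaf
  probabilities.

Both models are evaluated by repeated tenfold cross-validation (100
repeats by default, with t-based 95% confidence intervals) and external
validation, reporting sensitivity, specificity and the rate of correct
classification (CCR) in percent.

The reference compound sets these methods were developed on are not
redistributable, so the package includes seeded synthetic generators with
planted class signal (enriched ppm windows; mean-shifted descriptor
blocks) that exercise every stage end to end. See the methods vignette
(`vignettes/sdar-decision-forest.Rmd`) for the model details, parameter
defaults, and what the synthetic benchmarks do and do not demonstrate.

## Worked example

Simulate spectra for 300 compounds with two enriched windows (carbon
48–50 ppm, nitrogen 230–240 ppm; Poisson rates 2.0 for inhibitors vs 0.1),
bin at C2&N10, fit a stepwise discriminant at F > 2.0, and cross-validate:

```r
library(sdarforest)

windows <- list(
  list(nucleus = "C13", lo = 48,  hi = 50,  rate_pos = 2.0, rate_neg = 0.1),
  list(nucleus = "N15", lo = 230, hi = 240, rate_pos = 2.0, rate_neg = 0.1))
ds  <- generate_spectra_dataset(spectra_sim_config(
         n_compounds = 300, planted_windows = windows, seed = 42))
occ <- build_occupancy_matrix(ds$records, ds$labels, c_width = 2, n_width = 10)
occ
#> occupancy_matrix: 300 compounds x 180 available bins (C2 & N10)
#>   positives (inhibitors): 105 of 300; 0 empty bins dropped

fit <- fit_stepwise_lda(occ, config = lda_fit_config(f_enter = 2.0))
fit
#> stepwise_lda: 36 variables selected (F > 2), n = 300, Wilks' lambda = 0.2352
#>    C2 (48–50), N10 (230–240), C2 (208–210), C2 (16–18), ...
```

Both planted windows head the selection. The per-bin report gives each
selected bin's class-mean occupancy (×100; 100 = one shift in the range
per compound) and the p-value of its F-to-remove in the final model:

```r
rep <- bin_report(fit, occ)
head(rep[order(rep$p_value), ], 2)
#>             bin mean_occupancy_0 mean_occupancy_1      p_value
#> 6    C2 (48–50)         26.66667        233.33333 2.665571e-30
#> 30 N10 (230–240)        12.82051        178.09524 2.626062e-28

repeated_cv(occ$counts, occ$labels,
            function(X, y) fit_stepwise_lda(X, y, lda_fit_config(2.0)),
            cv_config(n_repeats = 10, seed = 1))
#> correct classification: 85.5 ± 0.9%
#> sensitivity:            74.4 ± 0.9%
#> specificity:            91.4 ± 1.2%
```

Inhibitors carry ~2 extra shifts in each window (mean occupancy 233 vs 27,
and 178 vs 13), and the cross-validated model recovers most of that signal
(CCR 85.5%). The decision-forest route works the same way from a
descriptor table: `shannon_entropy_filter()` → `fit_forest()` →
`predict()` / `repeated_cv()`.

A thin command-line front end drives the same functions from YAML or JSON
configs (tasks: `simulate`, `bin`, `train-sdar`, `train-df`, `cv`,
`validate`, `report`):

```sh
Rscript inst/cli/sdarforest.R --config run.yaml --task cv --seed 7 --out-dir results
```

Every run writes a `provenance.json` (config echo, package version, seed),
and identical invocations produce byte-identical artifacts.

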