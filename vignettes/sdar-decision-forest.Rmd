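---
title: "Spectral and structural classifiers of CYP inhibition: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral and structural classifiers of CYP inhibition: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The modeling problem

Whether a drug-like compound inhibits a hepatic cytochrome P450 isozyme
(CYP3A4 or CYP2D6) determines much of its drug–drug interaction liability.
`sdarforest` implements two complementary binary classifiers of
inhibitor/non-inhibitor status:

* **SDAR** (spectral data–activity relationship): the compound is described
  by its predicted ^13^C and ^15^N NMR chemical shifts, turned into binned
  occupancy counts; the classifier is a two-class linear discriminant with
  forward stepwise variable selection.
* **SAR** via a **decision forest**: the compound is described by a numeric
  molecular-descriptor table; low-information descriptors are removed by a
  Shannon-entropy filter and the classifier is a consensus of Gini-split
  decision trees built on mutually disjoint descriptor subsets.

Both are evaluated the same way: repeated tenfold cross-validation on the
training set and external validation on a held-out set, reported as
sensitivity (inhibitors recognized), specificity (non-inhibitors
recognized), and the rate of correct classification (CCR), each in percent.

The reference compound collections these methods were developed on (a
602-compound training set with 36% CYP3A4 and 26% CYP2D6 inhibitors, and a
100-compound external set) are not redistributable, and neither are
commercial shift predictions or descriptor batteries; the package therefore
ships seeded synthetic generators that emulate the *shape* of those inputs
so the full pipeline is exercised and tested end to end.

# Spectral binning

Each compound contributes a list of carbon shifts (ppm, typically 0–240)
and zero or more nitrogen shifts (0–600 ppm). A binning scheme pairs a
carbon width with a nitrogen width; the supported schemes are C1&N5, C2&N10
and C3&N15 (1/2/3 ppm carbon with 5/10/15 ppm nitrogen). Intervals are
half-open and lower-edge inclusive, anchored at 0 ppm, so every shift maps
to exactly one bin and a compound's row sums to its shift count per
nucleus. Labels show the lower edge for unit-width bins ("C1 (45)" is
[45, 46)) and the range otherwise ("C3 (48–51)" is [48, 51)).

Three conventions are worth making explicit because no standard fixes them:

* Edges are lower-inclusive. A shift at exactly 48 ppm belongs to
  C3 (48–51), never to C3 (45–48).
* Out-of-range shifts (negative, above 240 or 600 ppm) are binned on the
  extended grid rather than clipped, so the conservation property
  (row sum = shift count) holds unconditionally.
* Nitrogen-free compounds get all-zero nitrogen features — the discriminant
  needs complete rows, and "no nitrogen" is chemical information, not
  missing data.

Columns that are empty across the whole dataset are dropped from the
feature matrix; the dropped labels are kept in metadata, and the remaining
column count is the "available bins" figure that selection is reported
against ("k selected / m available"). Counts enter the model as raw
integers; occupancies above one per compound are retained (class-mean
occupancies are reported scaled by 100, so 100 means one shift in the range
per compound and values above 100 are possible).

# Forward stepwise linear discriminant analysis

For a variable subset S, Wilks' lambda is
\[
\Lambda_S = \frac{\det W_S}{\det T_S},
\]
with \(W\) the pooled within-class and \(T\) the total cross-product
matrix. The marginal contribution of variable \(v\) given S (two groups,
\(n\) compounds, \(p = |S|\)) is the partial F
\[
F = (n - 2 - p)\left(\frac{\Lambda_S}{\Lambda_{S \cup v}} - 1\right)
\]
on \((1,\, n - 2 - p)\) degrees of freedom; with \(S = \emptyset\) this is
the one-way ANOVA F. Selection is classic forward stepwise: enter the
best candidate while its F exceeds `f_enter`, then remove any selected
variable whose F-to-remove falls below `f_remove`, until no entry
qualifies, degrees of freedom run out, or `max_steps` is hit. The two
thresholds are coupled by default (`f_remove = f_enter`), matching the
convention of the discriminant-analysis software this procedure mirrors;
both can be set independently. The thresholds of practical interest are
0.5 (permissive) and 2.0 (conservative): the permissive setting roughly
doubles the number of selected bins.

The final model is an ordinary two-class LDA on the selected set: scores
\(\delta_k(x) = x^\top\Sigma^{-1}\mu_k - \tfrac12\mu_k^\top\Sigma^{-1}\mu_k
+ \ln\pi_k\) with pooled covariance \(\Sigma = W/(n-2)\) and, by default,
**equal priors** \(\pi_0 = \pi_1 = 0.5\). Equal priors deliberately ignore
the class imbalance of the training collections — with empirical priors a
26%-prevalence model buys accuracy by calling almost everything a
non-inhibitor, which is useless for flagging inhibitors.

Numerical choices:

* The engine keeps the full \(W\) and \(T\) matrices and evaluates entry
  and removal F values through Schur complements of the selected block
  (F-to-remove comes from the diagonal of the block inverses), which is
  algebraically identical to the determinant ratios but one order cheaper
  per step. Tests cross-check it against the naive determinant oracle.
* A candidate whose within-group tolerance (1 − R² against the selected
  set, computed from \(W\)) is below `tolerance` (default 10⁻⁴) is skipped;
  integer count features are often nearly collinear. A candidate whose
  entry leaves the within block numerically unfactorable is banned and the
  next-best is tried.
* Ties on partial F break to the lower column index, so fits are
  deterministic.
* The per-variable p-value reported for a fitted model is the p-value of
  that variable's F-to-remove in the final model, df \((1, n - 1 - |S|)\).
  This is one reasonable reading of a "model p-value" per bin; no formal
  definition exists to match.
* If no variable ever qualifies, the model is valid but empty and predicts
  the non-inhibitor class at posterior 0.5 — the specificity-conserving
  fallback. Posterior ties in general classify as non-inhibitor.

Because LDA is affine-equivariant, occupancy counts are used
unstandardized; rescaling a column changes coefficients but no decision.

# The decision forest

Descriptors first pass a Shannon-entropy filter: each column is histogrammed
into `n_bins` equal-width bins (default 10) over its observed range and
\(H = -\sum_i p_i \log_2 p_i\) is compared against `min_entropy` (default
0.5 bits). Constant columns have \(H = 0\) and always fall. The filter is
idempotent and its report lists every descriptor's entropy. The defaults
are calibrated to separate near-constant junk from informative columns at
realistic table sizes; the original 777 → 353 reduction on the reference
descriptor battery is data-specific and not a target.

Trees are grown by recursive binary partitioning. At a node, every
available descriptor is scanned over the midpoints between consecutive
distinct sorted values; the split maximizing the decrease in Gini impurity
\(G = 1 - \sum_k p_k^2\) (size-weighted over the children) is taken, with
ties broken toward the smallest threshold. Growth stops at pure nodes,
nodes smaller than twice `min_leaf` (default 5), or when no split improves
by more than `min_decrease` (10⁻⁶). A tree may use at most
`max_descriptors` (17) distinct descriptors — once at the cap, further
splits may only reuse them — and trees ending below `min_descriptors` (6)
are flagged. These stopping rules are the package's own calibration chosen
so trees on realistic synthetic tables land in the 6–17 descriptor range
that the consensus models are known to use; no pruning is applied beyond
them.

The forest is an **ordered** ensemble (default five trees): tree *t* is
grown with every descriptor used by trees 1…*t*−1 excluded, making the
trees distinct but comparable — descriptor sets are pairwise disjoint by
construction. Fitting stops early (with a warning) if a new tree cannot
reach `min_tree_accuracy` (default 0.5) on the training data from the
remaining descriptors. The consensus probability is the unweighted mean of
the trees' leaf probabilities; the label is inhibitor iff it exceeds 0.5,
ties going to non-inhibitor.

# Evaluation protocol

`repeated_cv()` randomly divides the data into ten portions (remainder
spread one per fold; unstratified by default, matching a plain random
division — a stratified option exists), holds each portion out once, and
repeats the whole division 100 times by default. Within a repeat, metrics
are computed on the pooled held-out predictions (micro-averaged);
`mode = "fold_averaged"` averages per-fold metrics instead, and the mode is
recorded in provenance since the two differ slightly when folds are
uneven. Across repeats the package reports the mean and a t-based 95%
confidence half-width (df = repeats − 1). If a training fold loses an
entire class the division is redrawn once, then the run fails loudly —
silently skipping such folds would bias the metrics. `external_validate()`
applies a fitted model unchanged to a held-out set.

CCR is always the prevalence-weighted mean of sensitivity and specificity,
\(\mathrm{CCR} = (P\cdot Se + N\cdot Sp)/(P+N)\); the test suite asserts
this identity on every report type.

# The synthetic-data generators

`generate_spectra_dataset()` emulates predicted-shift inputs: per compound,
5–40 carbon shifts uniform on [0, 240) ppm and 0–6 nitrogen shifts on
[0, 600) ppm with a 20% chance of none; labels are Bernoulli with the
training-collection fractions (0.36 default, 0.26 for the second isozyme).
Class signal is planted as ppm windows in which a compound receives extra
Poisson-distributed shifts at a class-specific rate, placed uniformly
within the window; the ground truth (windows, rates, and the planted shift
values themselves) is returned for recovery checks.
`generate_descriptor_dataset()` emulates a descriptor table (777 columns
default): informative columns are standard normal with the inhibitor class
mean-shifted by a configurable standardized effect size, optionally in
correlated blocks sharing a latent factor; constant columns can be appended
to exercise the entropy filter.

These generators are statistically, not chemically, realistic. Uniform
backgrounds have no spectral fine structure, shifts within a compound are
independent (real functional groups produce correlated multiplets), and
descriptor tables lack the heavy tails and discreteness of real descriptor
batteries. Passing tests therefore demonstrate that the algorithms recover
planted structure and stay calibrated under their stated assumptions — not
that any particular accuracy will be reached on real chemistry.

# Study conditions used by the packaged experiments

The test suite and `scripts/acceptance.R` run the pipeline at fixed,
package-chosen problem sizes:

* *Spectral recovery*: n = 300 compounds, C2&N10 binning (about 180
  available bins), five planted windows (four carbon, one nitrogen) with
  per-class rates 2.0 vs 0.1, selection at F > 2.0, 50 seeds. All five
  corresponding bins are expected among the selected variables in at least
  90% of seeds.
* *Forest recovery*: n = 300, 100 descriptors of which 40 informative in 5
  correlated blocks (ρ = 0.8, d = 1.5) plus 5 constant columns. The
  planted pool must outlast five greedy trees — each tree typically
  consumes 7–10 informative descriptors, which is why 25 planted columns
  are not enough for the fifth tree to see signal.
* *Null calibration*: label-independent spectra, balanced classes,
  n = 300, C3&N15, F > 2.0, tenfold CV over 10 independent datasets × 10
  repeats (100 repeats of tenfold CV in total). Balance matters: with
  equal priors the chance level is exactly 50% by label-exchange symmetry.
  Two empirically important effects are worth recording. First, the
  *conditional-on-dataset* mean of repeated CV varies by ±2–3 points
  around 50 for a selector this aggressive (repeats reuse one realized
  dataset, and stepwise selection partially memorizes its accidental
  correlations), so the calibration averages over independent datasets
  rather than trusting a single draw; the same phenomenon produces the
  very wide CV confidence intervals seen with fine (1 ppm) binning.
  Second, under imbalanced labels (e.g. 36% positives) equal-priors LDA
  shows a small finite-sample majority-class bias of roughly +1 to +3 CCR
  points on null data, because the minority mean is estimated more noisily;
  this is a property of the estimator, not an implementation artifact.

# Known limitations

* Two classes only; no quadratic discriminant, no multi-class forest.
* The stepwise loop never removes the last remaining variable; a
  single-variable model whose F later degrades is kept rather than emptied.
* Tree growing is greedy: balanced XOR-type interactions with exactly equal
  cell counts have zero first-level Gini gain and cannot be entered.
* Consensus is an unweighted mean over trees; no quality weighting.
* Confidence intervals for repeated CV are t-based over repeat means;
  repeats share the dataset, so these intervals describe fold-assignment
  variability, not dataset-level uncertainty.
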