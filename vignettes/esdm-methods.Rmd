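---
title: "Methods: ensemble habitat-suitability modelling with esdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble habitat-suitability modelling with esdm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esdm)
```

# The problem

Presence-only wildlife records (typically camera-trap detections) and a set
of environmental raster covariates are the usual raw material of
habitat-suitability assessment in protected areas. `esdm` implements an
ensemble species distribution model (ESDM) pipeline for this setting:
several base learners are trained on presence versus pseudo-absence data,
evaluated by repeated holdout, filtered by a discrimination threshold, and
combined with accuracy-proportional weights; finally, single-species
suitability maps are merged into one conservation-priority surface by
weighting each species with its conservation value.

This vignette documents the model and its assumptions, the numerical
conventions, what the synthetic-data generator does and does not emulate,
and the design decisions taken where the methodology left genuine freedom.

# Grid and raster conventions

All layers live on one square-celled grid (`grid_spec`): row-major
indexing, origin at the top-left corner, rows increasing southward,
coordinates referring to cell centers, and point-to-cell mapping with
half-open intervals (a point on a cell's west or north edge belongs to that
cell). Two grids are aligned when every field except the CRS tag matches.
Rasters are exchanged as plain-text ESRI ASCII grids; because that format
has no layer semantics, the continuous/categorical role of each layer is
declared in a JSON stack manifest. A stack's valid mask is the conjunction
of per-layer data masks: a cell enters any computation only if every layer
has data there.

Terrain derivatives use Horn's 8-neighbour finite differences — the
de-facto standard of mainstream GIS slope tools — with replicated borders.
Aspect is reported as the compass bearing of the downslope direction
(degrees clockwise from north), with flat cells flagged `-1`. Slope and
aspect at a nodata cell are set to nodata even though the Horn kernel
itself omits the center cell. Distance-to-road layers are exact Euclidean
distances between cell centers after rasterizing road segments with a
Bresenham traversal; sub-cell geometry is deliberately ignored, matching
the raster resolution of the rest of the stack.

# Collinearity screening

Screening applies two rules to the continuous layers, computed over valid
cells only:

1. **Pairwise Pearson filter** (`|r| >= 0.7`, absolute value — the sign of
   a correlation is irrelevant to collinearity). Greedy: while any pair
   violates the threshold, the worst pair is located and the member with
   the larger mean absolute correlation to all remaining variables is
   dropped; ties drop the later variable in input order, so the procedure
   is deterministic.
2. **Iterative VIF filter** (`VIF >= 10`), with
   `VIF_j = 1 / (1 - R^2_j)` from the OLS regression of layer *j* on all
   other kept layers (standardized, intercept included). The largest VIF is
   removed until all fall below the threshold; exact collinearity yields an
   infinite VIF and is removed first.

The two rules are stated jointly ("VIF exceeding 10 **or** correlation of
0.7 or higher") without an order in the methodology this package
re-implements; the pipeline runs the correlation filter first, then VIF,
matching the common usdm-style workflow. Categorical land-use layers are
exempt from both screens and always retained, since Pearson correlation and
VIF are undefined for nominal codes. Screening is invariant to affine
rescaling of the layers.

# Occurrences and pseudo-absences

Presence points are snapped to their containing cells and deduplicated to
one record per cell by default — camera stations resampled into the same
cell would otherwise pseudo-replicate. Pseudo-absences are drawn uniformly
without replacement from the valid cells excluding presence cells,
count-matched to the presences, once per species per run; the seed is
recorded on the occurrence set. Excluding presence cells avoids
contradictory labels at identical covariate values; matching counts makes
the classes exactly balanced, so no class weighting is needed downstream.
No spatial thinning, target-group backgrounds, or bias layers are
implemented.

# Base learners

All three learners share one contract: `fit_sdm(algorithm, X, y,
hyperparams, seed)` and `predict_sdm(fit, stack)`, deterministic given
their inputs, with probabilities in [0, 1]. Continuous features are
standardized with training statistics; a categorical layer is one-hot
expanded over the codes present in the stack, so training and prediction
schemas agree.

- **maxent_like** — the standard logistic re-implementation of MaxEnt's
  presence/background model: L1-regularised logistic regression (glmnet)
  on linear plus quadratic expansions of the continuous covariates.
  The penalty is chosen by 5-fold cross-validation with seed-derived fold
  assignments (`lambda.min`). A design with fewer than two varying columns
  falls back to an intercept-only model.
- **random_forest** — an in-package CART forest (Rcpp): 500 trees, Gini
  splits, bootstrap resampling, square-root feature subsampling, minimum
  node size 5, probability output as the fraction of tree votes (tied
  leaves vote 0.5). The forest uses its own mt19937 stream seeded from the
  supplied seed, independent of R's RNG.
- **svm** — an RBF-kernel L2 (squared-hinge) support vector machine solved
  in the primal over the kernel expansion, `gamma = 1/p` by default, with
  Platt-scaled probabilities. The sigmoid is fitted on an internal 25%
  calibration split (decision values from a model trained on the
  complement) and applied to the full-data machine. Squared-hinge optima
  have sparse expansion coefficients, which is exploited at prediction
  time.

Defaults are deliberately plain because the source methodology states no
hyperparameters; every one is overridable through the `hyperparams`
argument and the pipeline config.

# Evaluation, admission and weighting

Each species is evaluated with `n_rep = 20` stratified 80/20 holdout
splits (the holdout takes `ceiling(0.2 n)` records per class), one fit and
holdout evaluation per algorithm per replicate, with replicate seeds
derived from the master seed. The source methodology mentions both
bootstrap repetition and an 80/20 split; this package implements the
split-without-replacement reading, with the replicate count configurable.

Two metrics are computed: AUC in the Mann–Whitney pairwise formulation
(ties half-counted) and TSS maximised over candidate thresholds (the
unique score values, predicting presence at `score >= t`); the smallest
threshold attaining the maximum is reported.

A model's admission statistic `r_i` is its mean holdout AUC over
replicates. Models with `r_i >= 0.85` are admitted (the boundary is
inclusive by default so that a model printed as 0.85 is not dropped;
strict mode is available), refit on all occurrence data, and combined as
`W_i = r_i / sum_j r_j` over the `h` admitted models. If no model is
admissible the species is reported unmodellable. Ensemble-level AUC/TSS
are computed by applying the weighted combination to each replicate's
holdout predictions and averaging; the AUC-weighted means of the member
metrics are reported alongside, since either reading of "ensemble
accuracy" may be wanted.

# Jackknife variable contributions

For each kept variable *v*, the admitted algorithms are refit with *v*
removed (same seeds, same ensemble weights) and the reduced ensemble map
is compared with the full map over valid cells:
`s_v = max(0, 1 - r(full, reduced))`, normalised to percentages. This is
the leave-one-variable-out correlation jackknife of SSDM-style ensemble
packages, not MaxEnt's training-gain jackknife — the two are not
interchangeable, and the choice is stated here because "default jackknife"
is package-specific. The leave-one-out ensembles reuse the full model's
weights rather than re-running the whole replicate evaluation per
variable: the contribution statistic compares predictions, not admission
decisions, and re-evaluating would multiply runtime twenty-fold.

# Conservation value and the multi-species overlay

Each species is scored on three ordinal scales: national protection level
(I 1, II 0.5, III 0.3, non-protected 0.1), Red List status (CR 1, EN 0.8,
VU 0.6, NT 0.4, LC 0.2, NE 0.1), and CITES appendix (I 1, II 0.6, III 0.3,
not listed 0.1). Blank entries mean the lowest category. The conservation
value is the plain mean `I = (I_grade + I_endangered + I_CITES) / 3`, and
the overlay weight of species *i* is `P_i = I_i / sum_j I_j`. Internal
arithmetic is unrounded; reports round to 3 decimals half-up (0.2131…
prints as 0.213). The overlay is the per-cell weighted sum of the
single-species maps, valid only where every map is valid — undefined
suitability cannot contribute. If a species is unmodellable its weight is
renormalised over the remaining species and the exclusion is logged in the
run report.

# Synthetic landscapes and virtual species

The generator emulates the structural features of the real covariate set
that the pipeline's behaviour depends on:

- spatially autocorrelated continuous fields (white noise smoothed with a
  separable Gaussian kernel of the stated correlation length, then
  standardized) — smoothing of white noise was chosen over spectral
  synthesis for dependency-light determinism;
- controllably correlated pairs, `mix · source + (1 - mix) · noise`, whose
  implied Pearson correlation is `mix / sqrt(mix^2 + (1 - mix)^2)` — used
  to exercise the screening rules on known ground truth;
- spatially coherent categorical classes (quantile-sliced smoothed
  fields);
- virtual species with logistic suitability
  `plogis(intercept + sum w_l resp_l)` with linear or Gaussian (unimodal
  niche) responses, and presence sampling proportional to true suitability
  (draws with replacement, deduplicated to cells — detections, not
  exhaustive surveys; the returned presence count can therefore fall
  slightly below the requested number of draws).

What it does **not** emulate: real topography, detection probability
(occupancy), spatial sampling bias along trails or roads, and measurement
error in the covariates. A green recovery test therefore establishes that
the pipeline recovers a species' known environmental signal under clean
sampling — not that any field dataset meets these assumptions.

The recovery fixture used in the acceptance suite is a 200 × 200 grid with
four autocorrelated layers and a virtual species driven dominantly by a
narrow Gaussian niche on one layer (weight 9, width 0.5 in standardized
units, intercept −5) plus a weak linear secondary (weight 0.8), sampled at
300 presence draws. The strong/weak asymmetry and the rarity (mean true
suitability ≈ 0.14) reflect the intended scenario — a species concentrated
in a distinct habitat — and were fixed before the acceptance thresholds
were evaluated; with a widespread species (intercept near 0) uniform
pseudo-absences overlap occupied habitat so heavily that no classifier, not
even the true suitability, can reach AUC 0.85, which is a property of the
sampling design rather than a defect of the learners.

# Numerical choices and degenerate inputs

- Nearest-neighbour resampling breaks exact center ties by R's `round`
  (half-to-even); tie geometry is avoidable by construction and flagged in
  the tests.
- A layer constant over valid cells has undefined correlations; it is
  flagged and removed at screening rather than silently kept.
- Perfect collinearity yields `VIF = Inf` and is removed first.
- TSS candidate thresholds are exactly the observed score values; when
  several thresholds attain the maximum the smallest is returned.
- All stochastic stages consume seeds derived deterministically from one
  master seed (`derive_seeds`), and `with_seed` restores the caller's RNG
  state, so a full pipeline run is bit-reproducible and replaying any
  stage from the run report reproduces its outputs.
- Jackknife scores are floored at zero (removing a variable can slightly
  *increase* correlation by chance) and a constant full or reduced map
  contributes a zero score with a warning.

# Known limitations

- Pseudo-absence contamination bounds attainable AUC for widespread
  species, as discussed above; prevalence-dependent metrics (TSS
  especially) inherit this.
- The base learners are fixed to the three stated families; GAM/BRT/ANN
  and hyperparameter tuning are out of scope.
- No reprojection between coordinate systems: all inputs must share one
  CRS, and alignment is purely grid arithmetic.
- Binary range maps, uncertainty (between-model variance) surfaces, and
  occupancy-style detection modelling are not produced.
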