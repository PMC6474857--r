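---
title: "Projecting climate-driven range loss and threat status with ensemble niche models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting climate-driven range loss and threat status with ensemble niche models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enmrisk)
```

## Scope and model

`enmrisk` estimates how much climatically suitable habitat a
range-restricted species (or a pooled phylogeographic clade) is projected
to lose under future climates, and converts that loss into an IUCN-style
threat category plus landscape-fragmentation diagnostics. The estimation
chain is the standard ensemble niche-modelling workflow:

1. presence records are spatially thinned to a pairwise minimum
   great-circle distance and pooled by clade;
2. background contrast comes from pseudo-absences sampled uniformly over
   the valid study grid;
3. predictors are screened for collinearity (pairwise |r|, then VIF);
4. four presence/background models (GLM, boosted trees, surface range
   envelope, MaxEnt-style penalized logistic) are fitted with
   class-balancing weights, scored by repeated stratified split-sample
   AUC/TSS, and combined by AUC-proportional weights;
5. the continuous ensemble is binarized at the minimal-predicted-area
   (MPA) threshold, masked for developed land, projected onto perturbed
   future climates under no-dispersal and unlimited-dispersal
   assumptions; and
6. losses are classified into threat levels and the binary ranges
   summarized by NP, PL, AI and SI.

The modelled quantity is climatic suitability only; the binary range is a
surrogate for the area of occupancy (AOO), counted in grid cells. At the
~1 km cell sizes this package emulates, cell counts differ from geodesic
areas by a near-constant factor inside a single study region, which
cancels in all percentage-based statistics.

## The fitting function

`enm()` is the package's central estimator. Given a training table it
runs the split-sample evaluation, refits every algorithm on the full
table, and returns a classed object with `print`, `summary`, `predict`,
`coef` and `plot` methods. Design points worth knowing:

- **Class weights.** Presences have weight 1 and each pseudo-absence
  weight `n_presences / n_absences`, so both classes contribute equal
  total weight to every likelihood. Evaluation metrics on the held-out
  rows are deliberately *unweighted*: AUC and TSS are reporting
  conventions, and the balancing weights exist only to keep the fitted
  probability surface from collapsing toward the background rate.
- **GLM.** Predictors are standardized (training mean/SD, stored with the
  model), candidate terms are each predictor and its square, and
  bidirectional stepwise selection minimizes AIC starting from the full
  model, so the selected AIC never exceeds the full model's.
- **GBM.** Bernoulli-loss gradient boosting with up to 2500 trees,
  learning rate 0.001, bag fraction 0.5, depth 3, seeded subsampling.
  These are deliberately conservative boosting settings: the small
  learning rate compresses raw predictions toward 0.5, which is harmless
  because downstream thresholding uses the ensemble's own occurrence
  suitabilities, not absolute probability calibration.
- **SRE.** The envelope is built from presences only: per predictor, the
  interval between the `q/2` and `1 - q/2` linear-interpolation quantiles
  with a total trim of `q = 0.05`. The trim is read as a *total* tail
  mass split across both tails (0.025 each), the common envelope
  convention; `trim_quantile` is exposed so any other reading is
  reproducible. Prediction is the conjunction of all interval tests, so
  SRE maps contain only 0 and 1.
- **MaxEnt-style.** The penalized presence–background logistic equivalent
  of maximum entropy modelling: an L1-penalized weighted logistic
  regression over linear, quadratic, pairwise-product and two-sided hinge
  features (4 data-derived quantile knots per predictor per direction).
  The penalty is selected by BIC along the regularization path — a
  deterministic, data-driven stand-in for MaxEnt's default regularization
  — and can be scaled with `reg_multiplier`. Optimization is capped at
  `max_iterations` (default 200) optimizer passes.
- **Consensus scores.** Reported AUC/TSS are held-out replicate means;
  resubstitution scores on the refitted full models are intentionally not
  reported because they are optimistically biased.

## Thresholding and projection

The MPA threshold is the minimum ensemble suitability over the occurrence
cells: the largest threshold at which every occurrence still falls in
predicted range. No "marginal" occurrences are removed, so the threshold
is a minimum statistic and inherits a minimum's sensitivity to the single
worst-predicted occurrence; this is the price of guaranteeing that the
predicted range contains every known record. The threshold is computed
once per clade on the current-climate ensemble and reused unchanged for
every future binarization. Ties (suitability exactly at the threshold)
count as suitable.

The human-footprint mask removes cells with footprint strictly greater
than 50 from current and future ranges alike. Under no dispersal, the
future range is intersected with the current one, so gain is identically
zero and `stable + loss = 100` in every summary row. Change statistics
are computed per GCM and then summarized (mean, SD across GCMs);
cellwise GCM-average maps are produced for display only.

## Threat levels and fragmentation metrics

Threat categories are a pure step function of projected loss: level 1 at
exactly 100%, 2 on [80, 100), 3 on [50, 80), 4 on [30, 50), and 0
("below assessment thresholds") under 30%, with inclusive lower
boundaries. The package emits the raw loss next to the level so users can
see proximity to a boundary; no interpolated sub-levels are defined.

Patch metrics use rook (4-neighbour) connectivity by default, matching
FRAGSTATS class-level conventions; queen adjacency is available via the
`connectivity` argument. AI is `100 g / g_max` with `g` the number of
shared edges between suitable cells and `g_max` the largest adjacency
count achievable by the same number of cells in a near-square block; it
is undefined (NA) for a single-cell class. SI defaults to the landscape
denominator (`A_L` = all valid cells); `denominator = "class"` is
available because "the landscape is subdivided" is ambiguous between the
two readings.

## The synthetic study conditions

The generator module exists so that every downstream stage can be tested
against known truth. Its defaults define the package's reference study
conditions:

- **Climate layers.** Six standardized pseudo-bioclim layers on a
  100×100 grid of 0.01° cells: smoothed Gaussian random fields
  (autocorrelation range 10 cells) plus gentle directional gradients.
  Two of the six are near-duplicates of base layers (scaled copy plus
  small noise, |r| ≈ 0.99), giving the correlation/VIF screen genuine
  work. The copies are *near*-duplicates on purpose: when two layers are
  interchangeable, it does not matter which member of the pair the screen
  keeps — which is exactly the assumption that justifies dropping one
  member of a collinear pair in real analyses. A noisier copy would be a
  lossy proxy of its base, and a model that kept it would be structurally
  blurred relative to the truth.
- **Virtual species.** A sharp unimodal quadratic-logistic niche on two
  climate axes (quadratic coefficient −30 on standardized bio1 and
  bio12; prevalence target 0.15, hit to ±0.02 by bisection on the
  intercept). The sharpness makes the suitability surface close to
  binary, i.e. a *separable* species: occurrence samples rarely fall in
  the thin transition zone, so the MPA threshold and the truth cutoff
  (0.5) select nearly the same range. Softer niches are scientifically
  interesting but are not the reference condition, because with heavy
  class overlap the MPA minimum statistic inflates the current range and
  biases loss fractions low.
- **Occurrences.** 300 cells sampled without replacement with probability
  proportional to true suitability (one record per cell, mimicking
  thinned field data), then thinned at 10 km.
- **Future scenarios.** Each GCM × RCP × period is an additive shift
  along the warming axis (bio1), scaled by severity multipliers
  0.5 / 0.75 / 1.0 / 1.5 for rcp45-2050 / rcp45-2070 / rcp85-2050 /
  rcp85-2070 and a base shift of 0.8 layer SDs, plus a per-GCM smooth
  noise field (SD 0.1) emulating between-GCM disagreement. Shifts are
  propagated coherently to collinear copies via `expand_shift()`:
  physically, variables that are collinear under the current climate move
  together under warming, and perturbing only one member of a duplicated
  pair would make climate change invisible to any model that retained
  the other member.
- **DEM and footprint.** A smooth ridged elevation surface with 3000 m of
  relief, and an integer 0–100 footprint layer whose fraction of
  developed cells (> 50) matches a target (default 0.1) by quantile
  construction, spatially clustered.

What the generator does *not* emulate: real WorldClim value
distributions, GCM physics, sampling bias in occurrence records,
dispersal barriers other than developed land, and biotic interactions.
Passing the synthetic benchmarks therefore demonstrates that the
*estimation machinery* is correct and unbiased under its own assumptions,
not that any particular real-world projection is accurate.

## Truth-recovery benchmark

The package's strongest self-test calibrates perturbations
(`calibrate_perturbation()`, 1-D root finding on the shift scale) so the
*true* no-dispersal loss — thresholding the true suitability at 0.5 on
current vs perturbed climate — equals 25%, 50% and 80% exactly, then runs
the full estimation pipeline blind and compares. At the reference
conditions (300 presences before thinning, 3,000 pseudo-absences, 3
evaluation replicates, noise-free calibrated scenarios) the estimated
loss tracks truth within ~5–10 percentage points in most seeds and is
always monotone in perturbation severity. The residual downward bias is
real and interpretable: the MPA range is slightly larger than the true
range, and a fixed-width transition band is a smaller fraction of a
larger area.

## Numerical choices

- Great-circle distances use the haversine formula with Earth radius
  6371 km; the thinning radius is a pairwise minimum-distance constraint
  enforced greedily over a seeded random permutation (idempotent on
  already-thinned sets).
- Quantiles everywhere are linear-interpolation order statistics (R type
  7); envelope bounds are sensitive to this, hence it is fixed and
  documented.
- Collinearity screening removes pairwise violations first (|r| > 0.75;
  from the worst pair, the member with the higher mean absolute
  correlation leaves), then VIF violations (largest VIF leaves while any
  exceeds 6). Ties break lexicographically by name, making the retained
  set independent of input column order. VIF of a perfectly collinear
  predictor is reported as `Inf`, not an error.
- Per-stage seeds are derived from the master seed and the stage name by
  a deterministic 32-bit hash, so adding a clade or a scenario never
  perturbs the random streams of the others, and every run is
  reproducible from `(config, seed)` alone — two runs with the same
  configuration produce byte-identical output manifests.
- Degenerate inputs are errors, not silent answers: empty current ranges
  (undefined percentages), single-class evaluation sets, occurrences all
  on nodata, all predictors removed by screening.
- Problem sizes used by the shipped test-suite benchmarks: unit tests run
  on 25–50 cell grids with a few hundred training rows; the evaluation
  benchmark uses the full reference conditions (100×100 grid, 10,000
  pseudo-absences, 10 replicates); the truth-recovery benchmark uses
  3,000 pseudo-absences and 3 replicates over 5 seeds. These sizes were
  chosen as the smallest at which the statistics of interest are stable.

## Known limitations

- Grids are simple lon/lat rasters with square cells; no projections,
  resampling or alignment tooling beyond exact-geometry checks. Raster
  I/O is plain-text ASCII grid plus a JSON stack manifest.
- The MPA threshold is a minimum statistic; with noisy occurrence data a
  single badly-predicted record inflates the predicted range. The paper
  workflow this package follows accepts that property deliberately
  (every occurrence must fall in predicted range), and so does the
  package.
- No spatial cross-validation; split-sample replicates are random, so
  spatial autocorrelation makes the reported AUC/TSS optimistic relative
  to spatially blocked evaluation.
- Dispersal is binary (none / unlimited); no kernels, no stepping-stone
  dynamics between periods.
- Threat levels implement only the four loss-based categories; no EOO
  polygons, generation-length scaling, or full IUCN criteria engine.
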