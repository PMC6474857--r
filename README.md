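# enmrisk

Ensemble ecological niche modelling, climate-driven range-loss projection,
and IUCN-style threat assessment — with a built-in virtual-species
simulator so the entire pipeline can be exercised and validated against
known truth without downloading any external rasters.

## The problem

Range-restricted mountain specialists (the motivating case is the mountain
vipers of the eastern Mediterranean, pooled into phylogeographic clades)
are projected to lose large fractions of their climatically suitable
habitat during the twenty-first century. Turning that projection into a
conservation statement takes a long chain of steps: occurrence thinning,
pseudo-absence sampling, collinearity screening, fitting several niche
models, weighting them into an ensemble, projecting onto perturbed future
climates, thresholding into presence/absence range maps, masking developed
land, applying dispersal assumptions, and finally classifying the
projected area-of-occupancy (AOO) loss into threat categories and
landscape-fragmentation metrics. `enmrisk` implements every step of that
chain as a tested, reproducible R pipeline.

## The core model

Habitat suitability is estimated by a weighted ensemble of four
presence/background models fitted to a table of `p` presences and `a`
pseudo-absences with class-balancing weights (presences weight 1, absences
weight `p/a`):

- **GLM** — weighted binomial regression on linear + quadratic terms with
  bidirectional stepwise AIC selection;
- **GBM** — stochastic gradient-boosted trees (up to 2500 trees, learning
  rate 0.001, bag fraction 0.5);
- **SRE** — surface range envelope (BIOCLIM): per-predictor presence
  quantile bounds, trim 0.05;
- **MaxEnt-style** — L1-penalized presence–background logistic regression
  over linear, quadratic, product and hinge features.

Each algorithm is scored by repeated (10×) stratified split-sample tests
(75% train / 25% test) with AUC and TSS; ensemble weights are
`w_i = AUC_i / Σ AUC`. The continuous ensemble map is binarized at the
**minimal predicted area (MPA)** threshold — the minimum ensemble
suitability at the occurrence points — so every occurrence falls inside the
predicted range. Cells with human-footprint values > 50 are masked as
developed. For each future scenario (GCM × RCP × period) the no-dispersal
range is `future ∩ current`; loss/stable/gain percentages are relative to
the current range, and the projected loss maps to threat levels

| loss (%) | level |
|---|---|
| = 100 | 1 |
| [80, 100) | 2 |
| [50, 80) | 3 |
| [30, 50) | 4 |
| < 30 | 0 (below assessment thresholds) |

Fragmentation is tracked with the number of patches (NP), proportion of
landscape (PL), aggregation index (AI = 100·g/g_max over rook
adjacencies) and splitting index (SI = A_L² / Σ a_i²).

## Worked example

A complete synthetic study — virtual species on a 100×100 climate grid,
300 sampled occurrences, 3,000 pseudo-absences, 5 evaluation replicates,
two emulated GCMs — runs in about a minute:

```r
library(enmrisk)

cfg <- enm_config(list(n_pseudo_absences = 3000, n_replicates = 5,
                       gcms = c("gcmA", "gcmB"), seed = 42))
run <- run_enm_pipeline(cfg)

summary(run$clades$virtual$model)
#>   algorithm n_replicates mean_auc sd_auc mean_tss sd_tss weight
#> 1       GLM            5    0.901 0.0285    0.762 0.0390  0.271
#> 2       GBM            5    0.835 0.0379    0.608 0.0803  0.251
#> 3       SRE            5    0.695 0.0587    0.390 0.1174  0.209
#> 4    MAXENT            5    0.890 0.0287    0.752 0.0346  0.268

print(run)
#> <enm_run> 1 clade(s), 16 scenario row(s)
#> Across-GCM no-dispersal loss summary:
#>    clade   rcp period mean_loss_pct sd_loss_pct
#>  virtual rcp45   2050      32.55662   0.8931227
#>  virtual rcp85   2050      65.33101   0.5543520
#>  virtual rcp45   2070      49.04181   1.3550827
#>  virtual rcp85   2070      85.64895   0.2155813

subset(run$risk, dispersal == "none" & rcp == "rcp85",
       select = c(gcm, period, loss_pct, threat_level, np, pl, si))
#>     gcm period loss_pct threat_level np     pl   si
#> 5  gcmA   2050     65.7            3 24 0.0787 1672
#> 7  gcmA   2070     85.8            2 25 0.0326 6075
#> 13 gcmB   2050     64.9            3 22 0.0805 1624
#> 15 gcmB   2070     85.5            2 24 0.0333 9937
```

Reading the output: every model except the envelope (SRE) clears
AUC > 0.8 and TSS > 0.6; projected loss grows from the moderate scenario
in 2050 (33%, below assessment thresholds) to the severe scenario in 2070
(86%, threat level 2), the between-GCM SD is small, and the surviving
range fragments (SI grows roughly four-fold from 2050 to 2070 while PL
more than halves). The same objects expose the full per-scenario tables
(`run$changes`, `run$risk`), the fitted ensemble
(`run$clades$virtual$model`, with `predict()`, `coef()`, `plot()`
methods), and the continuous suitability maps.

Individual stages are ordinary functions — `thin_occurrences()`,
`select_predictors()`, `enm()`, `mpa_threshold()`, `binarize()`,
`apply_footprint_mask()`, `apply_dispersal()`, `range_change()`,
`threat_level()`, `landscape_metrics()` — and work on user-supplied data
(ASCII-grid rasters + CSV occurrences) as well as on the synthetic
generators.

## Documentation

The methods vignette (`vignettes/range-loss-assessment.Rmd`) describes the
statistical model, the synthetic study conditions, every tunable
parameter, the numerical choices and the known limitations.
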