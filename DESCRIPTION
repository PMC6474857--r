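Package: enmrisk
Title: Ensemble Niche Modelling, Climate-Driven Range Loss and Threat Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits weighted ensembles of ecological niche models (GLM with
    stepwise AIC selection, gradient-boosted trees, surface range envelope,
    and a penalized MaxEnt-style presence-background model), evaluates them
    by repeated split-sample AUC and TSS, projects habitat suitability onto
    perturbed future climates, binarizes projections with the minimal
    predicted area threshold, applies human-footprint masks and dispersal
    scenarios, and converts projected range losses into IUCN-style threat
    levels and landscape-fragmentation metrics (number of patches,
    proportion of landscape, aggregation index, splitting index). A
    virtual-species module generates spatially autocorrelated synthetic
    climate grids, digital elevation models, human-footprint layers and
    occurrence samples so the entire pipeline can be exercised and
    validated against known truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    geosphere,
    glmnet,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
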