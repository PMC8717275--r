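Package: habrich
Title: Habitat-Type Richness on Equal-Area Grids: Simulation, Normalization,
    and Spatial Model Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the drivers of habitat-type richness on
    equal-area monitoring grids such as the 10 km x 10 km European
    Environment Agency reporting grid.  The package simulates synthetic
    landscapes with known generative truth (habitat occupancy, bioclimatic
    fields, terrain, population, fragmentation, street networks), counts
    and area-normalizes habitat richness with a log-log species-area style
    correction, derives a terrain ruggedness index from a digital elevation
    model, assembles and screens per-cell covariates, fits a generalized
    linear model, a generalized additive model, and a boosted regression
    tree ensemble with residual-autocovariate correction for spatial
    autocorrelation, and decomposes the fits into variable importance,
    inflated response curves, and double-centered interaction surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    xgboost,
    lhs,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
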