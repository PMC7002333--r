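Package: snowsync
Title: Spatiotemporal Modelling and Spatial Synchrony of Snow-Track
    Census Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing wildlife-triangle snow-track censuses of
    boreal mammals: simulation of census networks with negative-binomial
    track counts driven by covariates and a separable Matern x AR1 latent
    Gaussian field; construction of a flat-top Gaussian predation-pressure
    kernel around raptor nests with AIC-based shape selection; covariate
    preparation including thin-plate-spline interpolation of masting cone
    crops and two-standard-deviation covariate scaling; an empirical-Bayes
    Laplace-approximation engine for hierarchical negative-binomial
    spatiotemporal models with WAIC model comparison and spatial-range
    extraction; and per-year Moran's I correlograms for quantifying
    spatial synchrony.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    Matrix,
    mgcv,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
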