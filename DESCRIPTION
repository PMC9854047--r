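Package: specar
Title: Bayesian Spectral Band Selection with Spatial Models for Grain
    Phosphorus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models grain phosphorus concentration in field-trial wheat from
    plot-level hyperspectral canopy reflectance.  Provides penalized B-spline
    resampling of raw spectra onto a coarse band grid, spike-and-slab Bayesian
    variable selection over the spectral bands under three error structures --
    independent, geostatistical with an exponential correlogram, and
    conditionally autoregressive (CAR) on the field adjacency graph -- fitted
    by Gibbs sampling with Metropolis-Hastings updates for the spatial
    dependence parameter.  Includes deviance information criterion model
    comparison, repeated-holdout cross-validation with model-based spatial
    prediction of held-out plots, classical vegetation-index baselines (SR,
    NDVI, GNDVI, SAVI, OSAVI), and a synthetic field-trial generator that
    emulates a 126-plot split-plot phosphorus trial.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    splines,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
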