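Package: genuseed
Title: Seed Variety Genuineness Detection from Hyperspectral and RGB Imaging
Version: 0.1.0
Authors@R:
    person("genuseed", "developers", email = "genuseed@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for deciding whether individual seeds belong
    to a declared target variety using VIS/NIR hyperspectral imaging and RGB
    seed scans. Reads ENVI-style hypercubes, calibrates raw intensity to
    reflectance against white/dark references, trims noisy spectral bands,
    segments seeds and extracts one mean spectrum per seed, computes a
    54-feature shape/color/texture table from RGB scans, selects
    characteristic wavelengths with the successive projections algorithm
    (SPA), trains binary random-forest, RBF-kernel support vector machine and
    multilayer-perceptron classifiers with cross-validated grid search, and
    iteratively updates the model by absorbing poorly recognized external
    varieties (accuracy-threshold active learning). A synthetic-data module
    generates reflectance spectra, hypercubes and feature tables with the
    statistical structure the analysis assumes, providing ground truth for
    testing every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    optparse
Config/testthat/edition: 3
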