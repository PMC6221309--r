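Package: osteotex
Title: Quantitative Surface Texture Analysis of Bone Use-Wear
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative use-wear analysis on bone surfaces from
    confocal height maps. Implements the metrological preprocessing chain
    (least-squares leveling, mold mirroring, robust outlier removal, hole
    filling, Gaussian S-filter denoising and degree-2 form removal), computes
    four ISO 25178 areal texture parameters from scratch (arithmetic mean
    height Sa, autocorrelation length Sal, arithmetic mean peak curvature Spc
    and upper material ratio Smr1), simulates a bone-wear experiment
    (manufacturing states, material-dependent wear over time, mold replicas,
    crossed specimen and lot structure), and fits a multilevel multivariate
    Bayesian mixed model with a Student-t observation level by MCMC, with
    WAIC model comparison, intraclass correlations and Mahalanobis
    goodness-of-fit diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    jsonlite,
    ggplot2,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
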