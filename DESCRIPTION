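Package: pwlmap
Title: Piecewise-Linear Chaotic Maps from Flow-Cytometry Density Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers one-dimensional piecewise-linear chaotic maps from daily
    time series of marker-expression probability density functions, as measured
    by flow cytometry on sorted stem-cell subpopulations. Solves the inverse
    Frobenius-Perron problem by constrained least-squares estimation of the
    transfer (Frobenius-Perron) matrix on a partition of the log-intensity
    axis, followed by a canonical semi-Markov map construction. Provides
    fixed-point and Lyapunov analysis of the fitted map, one-parameter
    bifurcation scans, ensemble simulation of density evolution with optional
    additive Gaussian noise, and a synthetic cell-sorting experiment generator
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    quadprog,
    optparse,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
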