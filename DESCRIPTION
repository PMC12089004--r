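Package: grnlandscape
Title: Epigenetic Landscapes of Gene Regulatory Networks via the
    Fokker-Planck Equation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Translates Boolean gene regulatory networks into continuous
    stochastic models of protein concentrations, approximates the
    stationary solution of the associated Fokker-Planck equation with a
    gamma mixture fitted by Monte Carlo weighted-residual collocation,
    derives the epigenetic landscape U = -log P, and validates models
    against experimental gene-coexpression matrices using matrix-distance
    statistics with random-matrix null distributions.  Ships the 12-gene
    Arabidopsis thaliana flower-morphogenesis network as a worked fixture,
    together with grid-based Fokker-Planck oracles for low-dimensional
    cross-checks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    Matrix,
    pracma,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
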