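Package: sharpland
Title: Potential Landscapes and Noise-Driven Sharpening of Gene Expression
    Boundaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic simulation of morphogen-driven two-gene regulatory
    circuits on a two-dimensional cell grid, steady-state Fokker-Planck
    solution of their probabilistic potential landscapes, barrier-height and
    mean-first-passage-time quantification of expression-state switching,
    and sharpening-index comparison of circuit topologies under parameter
    perturbation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    MASS,
    optparse
Config/testthat/edition: 3
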