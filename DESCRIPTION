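Package: whorlsim
Title: Cell-Based Simulation of Whorled Organ Patterning on the Floral Meristem
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A coupled model of polar auxin transport and cell-based tissue
    growth on a radially expanding floral meristem. Cells are polygons in a
    planar vertex model relaxed by Metropolis Monte Carlo; per-cell auxin and
    PIN efflux-carrier cycling follow an up-the-gradient concentration-based
    transport system integrated with an explicit fifth-order Runge-Kutta
    scheme. Includes auxin-dependent target-area growth, cell division on
    area doubling with state inheritance, boundary auxin influx gated by a
    cell-count window, detection and whorl classification of auxin-maximum
    clusters (sepal, petal, reproductive), batch robustness statistics,
    parameter-sensitivity sweeps, and mutant parameter presets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
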