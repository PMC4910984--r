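Package: tumordecay
Title: Fractional Cell Kill Kinetics and Decay Dynamics of Solid Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the rate at which a solid tumor is lysed by cytotoxic
    lymphocytes. Implements a saturating (Hill-type) fractional cell kill
    law with a tumor exponent nu, its linear, exponential and parabolic
    decay limits, analytic and numerical layer-erosion geometry for disks,
    ellipses and arbitrary rasterized shapes, a two-phase cellular automaton
    (nutrient-limited avascular growth followed by frozen-tumor immune
    lysis), a single-lymphocyte random-walk toy model, and least-squares
    discrimination between power-law and exponential decay on lysis time
    series.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
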