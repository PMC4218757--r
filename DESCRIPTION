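Package: oring
Title: O-Ring Statistics and Spatial Association Analysis for Stem-Mapped
    Forest Plots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Spatial point-pattern analysis for fully mapped forest census
    plots. Implements the relative neighborhood density statistic (the
    abundance-scaled O-ring, Omega_r), the Omega_0-10 aggregation-intensity
    index, the bivariate ring pair-correlation statistic g12(r), Monte Carlo
    complete-spatial-randomness envelopes with a three-way classification of
    patterns and associations, diameter-class aggregation profiles, and
    genus-level pooling of congeneric species. Edge correction uses exact
    closed-form circle-rectangle intersection areas. A synthetic community
    generator (conditional-total Thomas cluster processes with configurable
    spatial segregation and diameter distributions) supports testing and
    method evaluation where census data cannot be shared.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
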