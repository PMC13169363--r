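Package: polwann
Title: Machine Learning of Periodic Polarization and Wannier Centers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for learning the electric polarization of periodic molecular
    systems. Implements data-driven branch unwrapping of multivalued polarization
    training data (probe models plus the Hartigan dip test), rotationally covariant
    kernel regression for global polarizations and per-atom Wannier-center
    displacement sums, Wannier-center assignment and bonded-pair repair, infrared
    spectra from dipole autocorrelation with shell-resolved decomposition, and
    hydrogen-bond network analysis of water-alcohol mixtures. Ships a synthetic
    fixture generator (idealized water/ethanol mixtures, Wannier center placement,
    wrapped polarization branches, harmonic dipole trajectories) so every method is
    testable without electronic-structure data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
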