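Package: cvmech
Title: Mechanism Classification for Cyclic Voltammetry from Simulated Voltammograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates cyclic voltammograms for the five common homogeneous molecular
    electrochemical mechanisms (E, EC, CE, ECE, DISP1) by solving the one-dimensional
    diffusion-reaction problem with concentration-dependent Butler-Volmer boundary
    conditions, samples electrochemically accessible systems across their kinetic zones,
    converts multi-scan-rate voltammogram sets into a fixed 6x3x500 normalized tensor
    representation, and trains residual convolutional network ensembles that output a
    five-component mechanism-probability vector. Includes gradient-based importance maps,
    noise and scan-rate-count robustness sweeps, confusion matrices, and an in-silico
    mechanism-transition analysis along the Saveant kinetic parameter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
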