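Package: enosebeer
Title: Electronic-Nose Calibration Pipeline for Ethanol Content in Beers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation, preprocessing, and chemometric calibration of a
    13-channel metal-oxide-semiconductor (MOS) gas-sensor array that
    estimates the ethanol content (% v/v) of beers from headspace
    measurements. Provides a seeded forward simulator of the sensor array
    under a fixed calibration/test protocol, an outlier-gated moving-average
    filter, polynomial temperature/humidity response compensation, min-max
    normalization, F-test based sensor pruning, four calibration regressors
    (multiple linear regression, log-transformed multiple nonlinear
    regression, extreme learning machine, random forest), and k-fold
    cross-validated evaluation against the Brazilian +/-0.5 vol. labeling
    tolerance.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    ranger,
    Rcpp,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
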