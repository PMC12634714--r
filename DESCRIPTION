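Package: sweat2blood
Title: Blood Glucose Estimation from Sweat Glucose Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for non-invasive estimation of blood glucose concentration
    time courses from sweat glucose measurements. Implements a one-dimensional
    compartmental convection-diffusion model of glucose transport from the
    blood capillary through the interstitial fluid and the sweat gland to the
    skin surface, characterises the transport system by its impulse response,
    reduces it to the three-parameter local density random walk (LDRW)
    indicator-dilution model via a log-domain multiple linear regression fit,
    and inverts sweat measurements to blood glucose with an alternating
    double-loop bounded optimisation. Includes evaluation metrics (RMSE, MAE,
    RMSPE, Pearson R, R squared, RMSD, AICc), Monte-Carlo parameter
    sensitivity analyses, and a synthetic paired blood/sweat data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    pracma,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lhs,
    optparse,
    jsonlite
Config/testthat/edition: 3
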