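Package: canemass
Title: Sugarcane Ground-Campaign Biomass Estimation and Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for converting non-destructive sugarcane biometrics
    (stalk height and diameter, cane counts, leaf area index) into cane
    biomass and tons-cane-per-hectare (TCH) yield profiles, following an
    allometric cylinder model calibrated against destructive sampling.
    Includes hierarchical logistic growth interpolators (a pooled general
    fit whose confidence bounds constrain per-field and per-sampling-unit
    re-fits), a three-tier precision framework (instrument operation,
    idealization, and function-fitting precisions) with first- and
    second-order delta-method error propagation, Monte-Carlo measurement
    perturbation bands for TCH profiles, empirical variograms of intensive
    transects, and a synthetic-campaign generator with known ground truth
    for end-to-end validation.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
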