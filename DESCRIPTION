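Package: leafhydraulics
Title: Leaf Hydraulic Traits from Pressure-Volume, Rehydration,
    Optical Vulnerability and Gas-Exchange Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to elaborate leaf water-potential isotherms
    (pressure-volume curves) into osmotic and elastic traits, compute leaf
    hydraulic conductance from rehydration kinetics, build and fit optical
    xylem-vulnerability curves from time-lapse image stacks, estimate the
    water potential of near-complete stomatal closure by a resampling
    procedure, and derive the stomatal safety margin. Curve models
    (reparameterized Weibull, sigmoidal, log-logistic) are fitted by bounded
    nonlinear least squares with percentile-bootstrap confidence intervals.
    A synthetic-data generator with closed-form ground truth supports
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
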