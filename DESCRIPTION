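Package: hbflux
Title: Finite-State Transition Analysis of Co-Varying Hemoglobin Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies voxel-time samples of resting-state hemoglobin
    time series (oxy- and deoxyhemoglobin concentration deviations from
    their temporal means) into ten co-varying finite states defined by the
    algebraic signs of the five hemoglobin-signal components, and
    quantifies the kinetics of transitions between states. Provides
    variable-dwell-time transition counting, transition probabilities,
    mean dwell lags and rate constants, per-transition component fluxes
    and transition masses, state occupancy (volume-fraction) statistics
    with a first-order kinetic model check, map-similarity indices,
    laterality-corrected inter-breast difference metrics with t-test and
    ROC/AUC maps, and a semi-Markov synthetic-data generator for
    end-to-end validation of every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
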