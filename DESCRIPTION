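Package: steerlimb
Title: Upper-Limb Neuromuscular Dynamics During Steering
Version: 0.1.0
Authors@R:
    person("steerlimb", "developers", email = "steerlimb@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for multichannel surface electromyography
    (EMG) recorded together with steering-wheel torque and angle during
    driving tasks. Extracts activation envelopes from raw EMG, segments
    trials into clockwise and counterclockwise steering episodes, and
    computes direction-resolved EMG-torque cross-correlations, amplitude
    statistics, muscle contribution ratios, EMG-to-torque time delays
    (lag at maximum absolute correlation), and steering-smoothness
    metrics (approximate entropy and sliding standard deviation).
    Includes a synthetic-cohort generator with known ground truth
    (direction-dependent gains, per-muscle lead times) for end-to-end
    recovery testing, plus a batch driver that aggregates per-subject
    results into cohort summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
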