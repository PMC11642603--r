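Package: dyadicdraw
Title: Simulation and Analysis of Dyadic Drawing Experiments with EEG Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to simulate and analyse paired drawing experiments in which
    two agents draw shapes either jointly or in parallel. Provides a
    synthetic-data generator for balanced trial designs, pen trajectories with
    controllable visuomotor interference, and epoched EEG with configurable
    condition patterns; trajectory resampling, shape classification, error
    screening and template-based distortion scoring; behavioural statistics
    and mixed-effects models; spatiotemporal multivariate decoding built on
    supertrial averaging, Ledoit-Wolf shrinkage linear discriminant analysis,
    stratified cross-validation and permutation null distributions; and
    channelwise decoding with cluster-based permutation inference over sensor
    space.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    splines,
    lme4,
    lmerTest,
    jsonlite,
    rhdf5,
    deldir
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
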