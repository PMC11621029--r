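Package: bflow
Title: Behavioral Flow Analysis of Pose-Estimation Tracking Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying rodent behavior from markerless
    pose-estimation tracking tables. Cleans and calibrates tracking data,
    derives per-frame kinematic features with temporal expansion, clusters
    frames into behavioral motifs with k-means, stabilizes cluster labels
    across experiments with a supervised classifier, and compares groups
    through their behavioral flow: transition matrices between clusters, a
    permutation test on the Manhattan distance between group-mean matrices,
    per-animal likeness scores with effect-size and power analysis,
    responder stratification, and 2D fingerprint embeddings of individual
    animals. Includes a synthetic-data generator with Markovian behavioral
    state structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    MASS,
    mgcv,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
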