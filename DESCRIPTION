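Package: phosnet
Title: Temporal Phosphosignaling Network Reconstruction and Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Reconstructs kinase-mediated phosphosignaling networks from
    time-series phosphorylation data. Provides significance scoring of
    replicate fold-change trajectories by paired t-tests, prize-based
    extraction of a source-connected subnetwork from a background
    interactome, temporal pathway synthesis into a directed (and partially
    signed) summary network with per-node activity windows, comparison
    against functional kinase networks, validation against kinase-inhibitor
    biochemical and permeability screen data, and degree-preserving
    randomization null models. Includes a synthetic-data generator with
    planted ground truth for end-to-end testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
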