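Package: raftscape
Title: Lipid Raft Lipidomics, Microviscosity and Agent-Based Membrane Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for lipid-raft lipidomic profiles from spinal
    cord tissue, contrasting disease (ALS) and control (NSL) groups. Provides
    derived composition indexes (unsaturation and peroxidability indexes,
    saturate-to-unsaturate, cholesterol-to-cholesteryl-ester and
    anionic-to-zwitterionic ratios), an effect-size statistical battery
    (Mann-Whitney U, Cohen's d forest tables, varimax-rotated PCA lipid
    signatures, per-group correlation heatmaps, slope-heterogeneity tests),
    Perrin-equation-based apparent microviscosity estimation from
    fluorescence anisotropy, a logistic-normal synthetic cohort generator
    with planted group effects and correlation structure, and an agent-based
    two-dimensional lattice membrane simulator with conservative Kawasaki
    dynamics that predicts lipid-raft size, abundance and mobility from bulk
    lipid composition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
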