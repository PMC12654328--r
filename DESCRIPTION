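Package: flychoice
Title: Individual-Level Analysis of Phototactic Choice in Fly T-Maze Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for repeated binary light/dark choices of
    individually tested flies in parallel T-maze (FlyVac-style) assays.
    Aggregates per-trial choice logs to per-fly light-choice probabilities
    and phototaxis indices, quantifies between-fly dispersion with the
    scaled median absolute deviation (MADn), and performs permutation
    inference on both location (permutation Kruskal-Wallis, pairwise mean
    contrasts) and dispersion (MADn range and pairwise |dMADn| tests) with
    Holm step-down correction and BCa bootstrap confidence intervals.
    Descriptive pooled-trial proportions with Wilson and MOVER-W intervals,
    pre-specified robustness screens (3-MAD outlier rule, lane/side balance
    diagnostics), and a beta-binomial synthetic cohort generator for
    calibration and power studies are included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot
Config/testthat/edition: 3
RoxygenNote: 7.3.3
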