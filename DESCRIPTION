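Package: colonytrack
Title: Single-Cell Lineage Tracking and Heterogeneity Analysis for
    Colony-Forming-Unit Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for quantifying clonal heterogeneity in sparse
    colony-forming-unit (CFU) assays imaged by time-lapse microscopy.
    Builds and validates cell lineage forests from object-number tracking
    matrices, computes per-frame cell geometry, neighbor statistics and
    colony-level convex-hull metrics, classifies cell fate (senescence),
    proliferative capacity, colony origin and twin-division asynchrony,
    and provides a filtered Spearman correlation / PCA statistical layer
    with Bonferroni multiple-testing control. Includes an agent-based
    simulator of colony formation with stochastic cell lifetimes,
    heritable spread-area dynamics, senescence and persistent migration,
    used to generate ground-truth experiments for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: grDevices, jsonlite, stats, tiff, utils, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
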