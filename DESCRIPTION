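Package: mesoUSC
Title: Molecular Differential Diagnosis of Pleural Mesothelioma from nCounter Panel Counts
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the molecular differential diagnosis of epithelioid
    malignant pleural mesothelioma (MPM) versus benign mesothelial hyperplasia
    (MH) from nanoString nCounter counts of a 117-gene custom panel. Implements
    RCC lane-file input/output, negative-control background subtraction,
    positive-control (technical) and housekeeping (biological) normalization
    with quality-control sample exclusion, per-gene Mann-Whitney differential
    expression with tie and continuity corrections, two-way hierarchical
    clustering on Pearson correlation distance, and the Uncorrelated Shrunken
    Centroid (USC) classifier with leave-one-out cross-validated hyperparameter
    selection. A negative-binomial cohort simulator generates nCounter-like
    two-class data so the whole pipeline is testable without access to the
    original cohort.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
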