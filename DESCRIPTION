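Package: hippmvpa
Title: Searchlight MVPA Decoding in Hippocampal Subfield ROIs with a
    Synthetic fMRI Cohort Generator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-voxel pattern analysis (MVPA) of region-of-interest fMRI
    data in the style used for hippocampal subfield decoding: per-trial
    beta-series estimation by ordinary least squares with a canonical
    double-gamma HRF, ROI-restricted searchlight feature selection scored by
    leave-one-out linear support-vector-machine accuracy, nested
    leave-one-trial-out decoding without selection leakage, cross-condition
    generalization, Dice-based segmentation reliability metrics, and
    group-level inference (one-sample and paired t-tests, one-way
    repeated-measures ANOVA, hemisphere collapse). Includes a synthetic
    cohort generator (subfield masks, event schedules, psychometric
    behavior, and BOLD with known embedded patterns) so the entire pipeline
    is testable end-to-end without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
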