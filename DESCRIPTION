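Package: stmdrift
Title: Delay-Period Drift Analysis for Trial-Structured Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analyzing two-photon calcium imaging recorded during
    delayed match-to-sample tasks. Provides a synthetic session generator with
    known ground truth, pixelwise GLM-based detection of event-related neurons,
    ROC-based preference/reliability/phase-selectivity indices with permutation
    validation, PCA trajectory distances and a trajectory similarity index,
    coding-direction projections with residual separation, and population
    decoding via linear-discriminant signal-to-noise ratios, support vector
    machines, and native-space correlations. Designed to quantify the drift of
    delay-period population activity toward the opposite stimulus
    representation on error trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    e1071,
    withr
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
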