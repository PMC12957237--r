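Package: scbam
Title: Sandwich-Enhanced Attention Networks for Finger Decoding from Ultra-High-Density EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decoding individual finger movements from ultra-high-density
    (256-channel) EEG. Implements the full offline pipeline: synthetic uHD-EEG
    session simulation on a regular electrode grid, preprocessing (z-score
    normalization, common average reference, Butterworth notch cascade, artifact
    rejection, overlapped windowing), filter-bank common spatial pattern (FBCSP)
    feature extraction, a convolutional classifier with sequential filter and
    spatial/rhythm attention in a sandwich configuration (SCBAM) plus its ablation
    variants, one-vs-one multiclass ensembling with two-stage tie-breaking, and an
    evaluation suite (accuracy, Cohen's kappa, trial-level permutation tests,
    paired t-tests, bootstrap confidence intervals, ROC curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    MASS,
    pROC,
    Rcpp,
    rlang,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
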