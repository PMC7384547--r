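Package: roicurate
Title: Semi-Automated Curation of CNMF-E-Extracted Calcium Imaging ROIs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control for regions of interest (ROIs) extracted from
    1-photon calcium imaging movies by constrained non-negative matrix
    factorization for microendoscopic data (CNMF-E). Reads spatial footprints
    and calcium traces from HDF5/MAT v7.3 containers, turns each ROI into a
    fixed-length feature vector (peak-centered footprint crop concatenated
    with a cropped, min-max normalized trace), trains and cross-validates
    include/exclude classifiers (decision tree, k-nearest neighbours, with
    optional PCA) under stratified k-fold cross-validation optimized on the
    F1 (or F-beta) score, and triages predictions by confidence so that only
    low-certainty ROIs need human review. Ships a synthetic-ROI generator
    with four corruption modes (rescaled footprints, noise-injected traces,
    both, and merged ROI pairs) for ground-truth benchmarking, plus
    evaluation tools: proportion confusion matrices, precision/recall/F-beta,
    interrater agreement, Cohen's d of classifier confidence for correct vs.
    incorrect predictions, and learning curves with PELT change-point
    detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    rhdf5,
    rpart,
    class,
    caret,
    EBImage,
    jsonlite,
    optparse,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
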