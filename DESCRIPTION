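Package: mfdfs
Title: Manifold Feature Fusion and Dynamical Feature Selection for
    Cross-Subject EEG Emotion Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements a cross-subject electroencephalography (EEG) emotion
    recognition pipeline built around manifold feature fusion and dynamical
    feature selection (MF-DFS). Provides a synthetic multi-subject EEG
    generator with class-dependent band power and subject-specific
    distribution shifts, database-style preprocessing (Butterworth filtering,
    re-referencing, downsampling, trial segmentation, three-class labeling of
    1-9 affective ratings), extraction of 364 classical and 128 differential
    entropy features from a 32-channel montage, neighborhood component
    analysis (NCA) feature weighting with leave-one-subject-out regularization
    selection, geodesic flow kernel (GFK) domain adaptation on the Grassmann
    manifold with subspace-disagreement dimension selection, a recursive
    feature elimination wrapper that re-selects features per held-out subject,
    and a leave-one-subject-out evaluation harness with tree-ensemble
    classifiers and paired t-test comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    S4Vectors,
    SummarizedExperiment,
    ranger,
    rpart,
    xgboost,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
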