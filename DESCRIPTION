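Package: odorclass
Title: Multi-Label Odor Classification from Molecular Spectra and Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting odor descriptors of volatile molecules from
    vibrational spectra, electron-ionization mass spectra and path-based
    molecular fingerprints. Implements Gaussian peak smoothing onto a bounded
    frequency scale, mass-spectrum windowing and normalization, multi-label
    imbalance measures (label cardinality and density, per-label imbalance
    ratio IRLbl, MeanIR, MaxIR, CVIR), multi-label random over- and
    under-sampling (ML-ROS, ML-RUS), iterative stratified train/test
    splitting, a cost-sensitive multilayer perceptron trained with focal
    loss, Binary Relevance and Classifier Chain decompositions with
    pluggable base learners, micro- and macro-averaged evaluation metrics,
    and Shapley-value feature attribution with per-class top-k aggregation.
    Includes a synthetic data generator that emulates the long-tailed label
    distribution and planted spectral signal of odorant datasets so the full
    pipeline can be exercised and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    pROC
Config/testthat/edition: 3
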