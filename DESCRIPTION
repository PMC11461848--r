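Package: neurofuse
Title: Hybrid 3D Deep Feature Fusion and Whale-Optimized Feature Selection
    for Multi-Class Brain MRI Classification
Version: 0.1.0
Authors@R:
    person("neurofuse", "authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A config-driven pipeline for three-class volumetric MRI
    classification (control / prodromal / Parkinson's disease). Two 3D deep
    feature extractors -- an ablation-selected seven-convolution 3D CNN and a
    fifteen-layer residual 3D network -- are trained on preprocessed volumes
    and tapped at their 1000-unit fully connected layers. Per-extractor
    feature vectors are merged by element-wise maximum, fused across
    extractors by regularized canonical correlation analysis, and reduced by
    whale-optimization wrapper feature selection with a KNN-error fitness.
    Classical classifiers (least-squares SVM, KNN, gradient boosting, random
    forest) are evaluated with stratified k-fold cross-validation. Includes
    synthetic volumetric phantoms, dual-view latent-factor generators, and
    planted feature-selection problems so the whole pipeline is testable
    without access-gated clinical data, plus PSO/GA/GSA/ACO baseline
    optimizers for convergence benchmarking. Volumes are read and written as
    NIfTI-1 files or uncompressed DICOM slice series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
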