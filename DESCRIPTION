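Package: fundusbalance
Title: Class-Imbalance-Aware Training and Evaluation for Retinal Fundus
    Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and evaluating four-class retinal disease
    classifiers (normal, glaucoma, age-related macular degeneration,
    diabetic retinopathy) under severe class imbalance. Implements corpus
    pooling across source datasets, a threshold-based two-stage training
    protocol (binary pre-training on excess majority-class images followed
    by balanced four-class fine-tuning with weighted cross-entropy), random
    over- and under-sampling baselines, and stratified k-fold
    cross-validation with one-vs-rest metrics and ROC bands. Ships a
    synthetic fundus image generator with class-conditional optic-disc,
    lesion and exposure structure so the full pipeline is testable without
    external data, and a compact self-contained convolutional network
    trainer (rectified-Adam, cosine-annealed learning rate, early stopping)
    suitable for desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    withr,
    png,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
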