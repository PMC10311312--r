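Package: mciconvert
Title: Recurrent Neural Network Prediction of Conversion from Mild
    Cognitive Impairment to Alzheimer's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Models conversion from mild cognitive impairment (MCI) to
    Alzheimer's disease (AD) from irregularly sampled longitudinal clinical
    visits combined with cross-sectional demographics.  Provides a
    longitudinal cohort container with CSV input/output, a synthetic cohort
    simulator with a latent-severity progression process, the full
    preprocessing pipeline (missingness filtering, diagnosis-constrained
    k-nearest-neighbour imputation, patient-level stratified splitting,
    min-max normalisation, window/horizon sequence construction), recurrent
    classifiers (GRU, LSTM, and their bidirectional variants, with a
    sequence-to-sequence decoder for multi-visit-ahead prediction) trained
    with a sensitivity-weighted binary cross-entropy loss and Adam, per-visit
    age as the carrier of irregular inter-visit time, scenario and ablation
    harnesses with F-beta evaluation, mean-aggregation baselines, and Shapley
    and permutation feature importance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    e1071,
    randomForest,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
NeedsCompilation: yes
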