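Package: copHMM
Title: Gaussian-Mixture Hidden Markov Models for Center-of-Pressure
    Balance-Control Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies quiet-standing balance recordings (center-of-pressure
    trajectories in the medial-lateral and anterior-posterior directions) as
    healthy or parkinsonian by training one Gaussian-mixture hidden Markov
    model per class and assigning each test subject to the class whose model
    yields the larger observation likelihood. Provides exact scaled
    forward-backward and Viterbi inference, K-means-initialised multi-sequence
    Baum-Welch estimation, stratified k-fold cross-validation with
    sensitivity/specificity/accuracy reporting, a hyperparameter sweep
    harness, delimited-text readers and writers for stabilometric recordings
    and cohort manifests, and a synthetic cohort simulator with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'cop-io.R'
    'emissions.R'
    'inference.R'
    'learn.R'
    'classifier.R'
    'copHMM-package.R'
    'serialize.R'
    'show-methods.R'
    'synthetic.R'
    'utils.R'
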