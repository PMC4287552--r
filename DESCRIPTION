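Package: phenoclass
Title: Comparative Cell-Phenotype Classification with Confusion-Driven
    Phenotype Merging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing cell-phenotype classifiers on image-derived
    feature tables from high-content screens.  Implements one-vs-all gentle
    boosting with regression stumps, L2-regularized L2-loss linear support
    vector machines (one-vs-all), radial-basis-function support vector
    machines (one-vs-one), and linear discriminant analysis with a
    Moore-Penrose pseudo-inverse pooled covariance, all behind a common
    fit/predict/posterior contract with Platt sigmoid calibration.
    Evaluation uses stratified k-fold cross-validation with nested grid
    search under class imbalance.  Averaged cross-validated confusion
    matrices are converted into a phenotype dissimilarity, clustered with
    UPGMA, and every classifier is re-evaluated along the resulting merge
    ladder from K phenotypes down to 2.  Additional analyses include
    repeated-CV consensus misclassification with overlap statistics,
    posterior-probability reject-option curves, and stratified subsampling
    learning curves.  A seeded synthetic generator produces imbalanced,
    confusable, optionally rank-deficient feature tables with a planted
    merge hierarchy so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    e1071,
    jsonlite,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
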