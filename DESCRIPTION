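Package: riemerp
Title: Riemannian Tangent-Space Decoding of Event-Related Potentials with
    Subclass-Regularized Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-stimulus decoding of event-related potentials (ERPs) from
    multi-channel EEG for screen-free brain-computer interfaces in which
    candidate objects in the environment are highlighted by a laser pointer.
    Windows time-locked to each highlighting are augmented with class
    prototypes after xDAWN spatial filtering, represented by Ledoit-Wolf
    shrunk covariance matrices, and classified in the tangent space of the
    symmetric positive-definite (SPD) cone under the affine-invariant
    Riemannian metric. Three pipelines are provided: a pooled tangent-space
    LDA, separate per-subclass classifiers, and a subclass-regularized LDA
    whose per-subclass tangent spaces are centered by parallel transport to
    the identity and whose class means are combined across subclasses by
    multi-target shrinkage (a small convex quadratic program). Includes a
    synthetic session simulator with controllable per-object ERP
    heterogeneity, a chronological cross-validation harness with window-level
    AUC, grand averaging, paired Wilcoxon comparisons with Holm-Bonferroni
    correction, and readers/writers for BrainVision recordings and tabular
    event schedules.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    signal,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
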