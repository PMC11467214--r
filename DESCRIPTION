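Package: cytoTensor
Title: Censored Canonical Polyadic Decomposition of Cytokine Signaling Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tensor-based systems analysis of cytokine signaling responses and
    receptor abundances measured by gated flow cytometry across subjects,
    treatments, cell types and markers. Implements canonical polyadic
    decomposition by censored alternating least squares with SVD
    initialization and Bro line-search acceleration, imputation-based and
    classification-based rank selection, jackknife factor-match-score
    stability, and downstream association statistics (L1-penalized logistic
    classification with repeated stratified cross-validation, permutation
    correlation tests, Mann-Whitney U, shrinkage partial correlations, ROC).
    Includes a synthetic cohort generator with known low-rank structure,
    cohort effects, noise and fiber missingness for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
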