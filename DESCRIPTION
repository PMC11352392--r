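Package: idhypergraph
Title: Individual-Deviation Hypergraph Subtyping of Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies subtypes within a patient group from regional
    brain-activity features (e.g., mean ALFF per atlas region) by modelling
    each patient through its vector of cosine deviations from every control
    subject, connecting patients with hyperedges learned by per-subject
    elastic-net sparse self-representation, partitioning the resulting
    hypergraph by maximizing a symmetric hypergraph modularity with a
    Louvain-style maximum-likelihood coordinate ascent, and evaluating
    subtype separability (pairwise RBF-SVM with cross-validation) and
    covariate-adjusted per-feature group differences with
    Benjamini-Hochberg FDR control. Includes synthetic cohort and
    planted-partition hypergraph generators so the whole pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    glmnet,
    quadprog,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
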