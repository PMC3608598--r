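Package: metalinprog
Title: Sparse Linear-Programming Support Vector Machines for Metagenomic
    Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simultaneous feature selection and class prediction for
    metagenomic count tables (OTU, taxon or pathway features) using
    linear-programming support vector machines: an L1-penalized hinge-loss
    model for binary phenotypes and a jointly L-infinity,1-penalized
    one-against-rest model for multiclass phenotypes, so that all
    per-class classifiers share one small set of discriminative features.
    Includes count normalization to relative abundances with square-root
    and arcsine variance-stabilizing transforms guided by Bartlett's test,
    cross-validated selection of the sparsity weight, a repeated
    stratified-split evaluation protocol with per-feature relevance
    counts, ROC/AUC utilities, and a Poisson-Gamma (negative-binomial)
    simulator with planted discriminative features. Optimization is done
    by an interior-point linear-programming backend written for the
    package, with a pluggable solver contract.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pracma,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
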