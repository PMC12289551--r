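Package: admixclass
Title: Supervised Admixture Projection and Continental Ancestry
    Classification for Sparse SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates per-individual genetic-ancestry component vectors
    from small, noisy SNP sets by projecting genotypes onto fixed
    gene-pool allele frequencies with an expectation-maximisation fit of
    the admixture likelihood, then classifies individuals into
    continental groups with a shrinkage linear discriminant analysis.
    Includes VCF filtering and panel intersection, threshold
    normalisation of ancestry profiles, stratified cross-validation with
    a full multi-class metric suite (one-vs-rest ROC and precision-recall
    curves with bootstrap bands, MCC, Cohen's kappa), and robustness
    experiments: SNP down-sampling correlation studies, foreign-SNP
    perturbation sweeps, and synthetic two-way admixture classification.
    A Balding-Nichols simulator generates differentiated gene pools and
    admixed cohorts with known ground truth so the whole pipeline runs on
    synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    nnet,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    MASS,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
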