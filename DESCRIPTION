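Package: stackgs
Title: Stacking Ensemble Genomic Prediction with GBLUP and BayesB Comparators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic prediction of breeding values from SNP genotypes using a
    stacking ensemble: support vector regression, kernel ridge regression and
    elastic net base learners operate on rows of a VanRaden genomic
    relationship matrix, and their out-of-fold predictions (metadata) are
    combined by an ordinary least-squares meta-learner. Includes marker
    quality control (MAF, call rate, Hardy-Weinberg equilibrium), genotype
    file readers (PLINK-raw, VCF, CSV), a quantitative-trait simulator with
    three genetic architectures, REML variance-component estimation with
    GBLUP, a BayesB Markov chain Monte Carlo sampler, and a K-fold
    cross-validation harness reporting Pearson prediction accuracy.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    data.table,
    e1071,
    glmnet,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
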