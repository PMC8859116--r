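Package: tetraGP
Title: Genomic Prediction for Polysomic Tetraploids with
    Genotype-by-Environment Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome-based prediction for autotetraploid crops such as
    potato. Converts tetraploid SNP allele dosages (0-4) into
    pseudo-diploid, additive tetrasomic and full-tetraploid (one-hot,
    non-additive) marker codings, builds linear (GBLUP) and Gaussian-kernel
    genomic relationship matrices, and fits single- and multi-environment
    Bayesian kernel regression models with genotype-by-environment
    interaction modelled through Hadamard-product covariances, by Gibbs
    sampling in the eigenbasis of each covariance component.  Includes the
    matching cross-validation schemes (random train/test partitions and
    CV2 multi-environment folds), truncation-selection utilities, and a
    synthetic tetraploid data generator so the whole pipeline can be
    exercised and calibrated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
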