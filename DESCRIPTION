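Package: caneGS
Title: Genomic Prediction for Early Clonal Selection in Staged Sugarcane Breeding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genomic selection in multi-stage clonal breeding
    programs such as sugarcane variety development. Provides a synthetic
    staged-trial data generator; genotype quality control (missing-rate and
    minor-allele-frequency filters, complete-LD deduplication, greedy LD
    pruning); pedigree (Henderson tabular), VanRaden additive, Vitezica
    dominance, Hadamard epistatic and single-step hybrid (H) relationship
    matrices; a REML mixed-model engine (EM with average-information
    acceleration, plus an exact spectral path for single-kernel models) for
    adjusted means (BLUEs), variance components and Holland broad-sense
    heritability with harmonic means; whole-genome prediction by extended
    GBLUP kernel combinations, rrBLUP, the Bayesian alphabet (BRR, Bayesian
    lasso, BayesA/B/C) via compiled Gibbs samplers, reproducing kernel Hilbert
    space regression, random forest and support vector machine adapters, and
    mixed linear model association scans whose significant markers enter
    GBLUP as fixed effects; multi-trait (Kronecker) genomic prediction of a
    compound trait with the target hidden in validation; and evaluation by
    k-fold and cross-stage validation with predictive ability and top/bottom
    coincidence indices, including marker-density sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    Rcpp,
    randomForest,
    e1071,
    vcfR
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr
Config/testthat/edition: 3
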