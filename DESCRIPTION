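Package: gpcurve
Title: Genome-Enabled Prediction Learning Curves with Bayesian Regression
    and Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable re-implementation of a two-step
    genome-enabled prediction study of a body-weight-like trait. Step one fits
    a pedigree animal model (EM/AI-REML variance components, Henderson BLUP)
    and pre-adjusts phenotypes for fixed and maternal permanent-environment
    effects; step two fits whole-genome regressions on standardized SNP
    dosages with from-scratch Gibbs samplers (Bayesian Ridge Regression and
    Bayes C-pi) and a multilayer perceptron trained with Adam, dropout and
    early stopping, including random architecture search. A synthetic
    population generator (pedigree, gene-dropped genotypes, trait with
    additive, maternal and residual components) stands in for proprietary
    data, and a nested training-set sub-sampling design compares the methods
    by prediction correlation, MSEP, relative gain, predictive bias, rank
    correlation and top-ranked agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
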