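Package: pcgp
Title: Principal-Component Genomic Prediction with Bayesian Shrinkage Priors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forward-in-time simulation of a livestock-style breeding
    population (historical mutation-drift phase followed by truncation
    selection on true breeding values), marker quality control, principal
    component analysis of the marker correlation matrix, and eight
    whole-genome regression models for genomic prediction: ridge-regression
    BLUP and Bayesian ridge, BayesA and BayesB on SNP genotypes, and
    eigenvalue-weighted, normal, scaled-t and double-exponential
    (Bayesian Lasso) principal-component regressions on PC scores, all
    sharing one design-matrix-agnostic core. Includes five-fold
    cross-validated accuracy, bias regression, and persistency-of-accuracy
    evaluation across selection-candidate generations, plus a scenario
    runner that reproduces the full simulation experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
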