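Package: cgmgp
Title: Crop Growth Model Assisted Genomic Prediction of Integrative Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Integrated crop-growth-model and genomic-prediction (CGM-GP)
    pipeline for sorghum aboveground fresh weight. Provides a sink-driven
    simulator of vegetative growth (thermal-time organogenesis on main stem
    and tillers, carbon supply/demand competition), Differential Evolution
    estimation of its eight genotypic parameters from trait trajectories,
    three whole-genome regression engines sharing one fit/predict contract
    (LASSO, a spike-and-slab Bayes C Gibbs sampler, and a 1D convolutional
    neural network), marker-based heritability via a VanRaden genomic
    relationship matrix and spectral REML, and a two-scenario evaluation
    harness (direct genomic prediction versus prediction through the crop
    model) under shared k-fold cross-validation. A synthetic-data module
    generates marker matrices with linkage disequilibrium, heritable
    genotypic parameters with additive and epistatic architectures, weather
    series and replicated noisy phenotype trials, so the whole pipeline is
    exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
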