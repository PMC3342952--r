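Package: inbredgp
Title: Genomic Prediction and Population Genetics for Fully Inbred Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-genome genomic prediction of quantitative traits in panels of
    fully inbred lines, such as the Drosophila Genetic Reference Panel. Implements
    GBLUP with maximum-likelihood variance components, RRBLUP back-solving of SNP
    effects, a BayesB marker-effect sampler with point-mass/scaled-inverse-chi-square
    mixture priors, grouped cross-validation designs with SNP-subset strategies,
    linkage-disequilibrium summaries and two effective-population-size estimators
    (Sved's LD formula and a modified Daetwyler accuracy curve with bias-corrected
    bootstrap intervals), REML variance-component models on individual records with
    additive and Hadamard-epistatic genomic covariances, and a sliding-window
    comparison of SNP-effect magnitudes against association anchors. A forward
    Wright-Fisher simulator with female-only recombination and full-sib inbreeding
    generates panels with the statistical structure these analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    Matrix,
    vcfR,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
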