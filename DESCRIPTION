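Package: fluctG
Title: Individual-Based Simulation of G-Matrix Evolution Under Fluctuating
    Trait Optima
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward-time Moran simulations of haploid (optionally sexual)
    populations with an evolving genotype-phenotype map: weight genes whose
    effects are routed onto quantitative traits by a heritable contribution
    matrix, under Gaussian stabilizing selection toward trait optima that
    fluctuate over generations in correlated, independent, or
    block-correlated patterns. Includes estimators of the total genetic
    variance-covariance matrix, its decomposition into pleiotropy and
    linkage-disequilibrium components by allele shuffling, additive
    (co)variance by midparent-offspring regression, mutational
    (co)variance matrices from single-mutation perturbations, and a
    fixed-pleiotropy evolvability transplant assay, together with the
    orchestration to compare environmental regimes at configurable scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
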