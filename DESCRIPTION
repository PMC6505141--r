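Package: kinherit
Title: Heritability Estimation with Pedigree, Realized and Genomic Kinship
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maximum likelihood estimation of narrow-sense heritability under
    the two-component polygenic random effects model, using a per-pedigree
    eigen-transformation of the fitted genetic correlation matrix. Provides
    the asymptotic sampling variance of the heritability estimate under
    correct model specification, and the pseudo-true limits (Kullback-Leibler
    minimizers) and sandwich asymptotic covariance of the estimates when the
    fitted correlation matrix differs from the truth. Includes gene-drop
    simulation of identity by descent along a genetic map, realized kinship
    matrices over arbitrary chromosome subsets, a synthetic founder-haplotype
    generator with marker genotype drop-down, the classic genomic relationship
    matrix, and a configurable simulation harness comparing empirical and
    analytical behaviour of the estimates across study designs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
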