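Package: haplogs
Title: Multi-Allelic Haplotype Genomic Prediction and Training
    Population Optimization for Inbred Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic selection toolkit for structured inbred breeding
    panels. Reads TASSEL-style HapMap genotypes, applies marker quality
    control and LD-kNN imputation, performs moving-grid spatial
    adjustment of field-trial phenotypes and REML estimation of
    broad-sense heritability, builds fixed-length multi-allelic
    haplotype blocks, computes genomic relationship matrices,
    identity-by-state distances, K-means population structure and
    adjacent-marker linkage disequilibrium, fits single-SNP and
    multi-allelic haplotype GBLUP models by restricted maximum
    likelihood, and evaluates predictive ability under k-fold
    cross-validation, stratified-sampling training-set optimization and
    leave-cluster-out validation. Includes a seeded generator of
    synthetic structured inbred populations for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
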