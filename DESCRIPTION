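Package: signetmod
Title: Network-Level Association of Mutational Signature Exposures with
    Expression Modules and Mutated Subnetworks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Treats per-patient mutational-signature exposures as continuous
    cancer phenotypes and associates them with gene networks in two
    complementary ways: consensus K-means clustering of gene-expression
    Spearman-correlation profiles with hypergeometric gene-set enrichment,
    and an exact search for connected, density-constrained subnetworks whose
    mutually exclusive alterations maximize a phenotype-association
    objective, with phenotype-permutation significance, module-size
    selection, and Benjamini-Hochberg FDR control. Includes multinomial
    mixture-model attribution of mutations to signature catalogs with
    cloud/dispersed separation, alteration-matrix construction with
    causality-oriented filters, and a synthetic-data generator that plants
    recoverable ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    mclust,
    withr
Config/testthat/edition: 3
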