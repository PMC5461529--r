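Package: epigain
Title: Gene Networks from SNP-Pair Epistasis in Case-Control GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds SNP-pair epistasis networks from case-control genotype
    data using mutual information and information gain against a binary
    disease trait, converts them into gene-gene interaction networks by a
    gene-size-unbiased maximum aggregation, extracts significant edges with
    a permutation-derived threshold and a sparsity scan, evaluates candidate
    networks by scale-free fit, hypergeometric enrichment and node AUC, and
    integrates the mutual-information and information-gain networks by
    union. Includes a seeded synthetic case-control GWAS generator with
    planted marginal and purely epistatic (XOR-type) effects, readers for a
    simple TSV genotype dialect and PLINK-style text files, and Cytoscape-
    compatible network exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
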