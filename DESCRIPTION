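Package: xenosplit
Title: Species-of-Origin Read Partitioning and Staged Differential
    Expression for Xenograft RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cross-species transcriptomics of experimental
    tumors grown on a host of another species, such as human
    hepatoblastoma cells on the chick chorioallantoic membrane (CAM).
    Simulates dual-species transcriptome references and sequencing reads
    with per-read truth, partitions reads by species of origin with a
    k-mer seeded classifier that discards reads mappable to both
    genomes, builds species-split gene-level count matrices, performs
    negative-binomial Wald differential expression with
    Benjamini-Hochberg correction and the conventional significance
    filter (adjusted p < 0.05 and |log2 fold change| > 1), provides
    variance-stabilizing transformation, PCA and hierarchical-clustering
    summaries, and scores semi-quantitative treatment phenotypes by
    observer consensus and chi-square testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    Biostrings,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
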