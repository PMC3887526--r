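Package: barseqr
Title: Design and Analysis of Bar-seq Pooled Mutant Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing and analysing Bar-seq experiments, in which
    pooled barcoded mutant libraries (such as the yeast deletion collection)
    are phenotyped by counting molecular barcodes in high-throughput
    sequencing reads. Provides Levenshtein-distance demultiplexing of sample
    indices and molecular barcodes, count filtering and aggregation across
    UPTAG/DNTAG barcodes and technical replicates, TMM normalisation,
    negative-binomial exact tests with empirical-Bayes dispersion shrinkage,
    Storey q-values, eigen-R2 variance partitioning, Wilcoxon rank-sum gene
    set enrichment, and a binomial read-subsampling engine for evaluating
    the power, accuracy, informativeness and false discovery rate of
    alternative replication and read-depth designs. A synthetic-experiment
    simulator generates realistic catalogues, count matrices and raw reads
    so the full pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
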