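Package: sweepscan
Title: Selective-Sweep Scans and Life-History Phenotyping for Partially
    Migratory Fish Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Window-based population-genomic scans separating migratory from
    freshwater-resident groups of a partially migratory fish: nucleotide
    diversity, Weir-Cockerham Fst and the reduction-of-diversity (ROD)
    statistic in genomic windows with joint empirical top-5% thresholding;
    identity-by-state distances and neighbor-joining trees for population
    grouping; per-SNP Fisher exact allele-frequency tests; coding-effect
    classification of variants; term enrichment of candidate genes; otolith
    Sr:Ca life-history classification; and 2^-ddCt relative-expression
    analysis. Includes a synthetic-data generator with planted sweeps for
    end-to-end validation, plus readers and writers for VCF, FASTA, GFF3,
    BED and Newick.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
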