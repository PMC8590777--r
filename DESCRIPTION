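Package: replongmeth
Title: Haplotype-Resolved Methylation and Tandem-Repeat Genotyping from
    Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for genotyping tandem-repeat expansions and profiling
    haplotype-resolved CpG methylation at a target locus from long reads
    that carry per-base 5-methylcytosine modification likelihoods.
    Projects read-level modification scores onto reference CpG positions
    through the alignment, calls per-site methylation by exact test or
    percent cutoff, rewrites reads as in-silico bisulfite conversions for
    browser display, genotypes repeat copy number and phases alleles by
    expansion size, decomposes repeat tracts into motif runs for waterfall
    plots, aggregates polymerase kinetics into per-position replication
    cycle times, and compares methylation profiles across samples
    (correlation, PCA, Ward clustering, per-base differential methylation
    with multiple-testing control). Includes a synthetic trio generator
    that emulates a maternal non-expanded allele, a paternal long mosaic
    hypermethylated expansion and an offspring contracted unmethylated
    expansion, so the whole pipeline is testable without sequencing data.
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
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
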