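Package: ddradkit
Title: Double-Digest RAD-Seq Locus Prediction, Read Processing, and
    Haplotype-Based Genotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for double-digest restriction-site
    associated DNA sequencing (ddRAD-seq). Predicts ddRAD loci by in silico
    double digestion of a reference genome for any pair of palindromic
    enzymes and fragment size window; demultiplexes and processes
    single-end reads (restriction-site reconstruction, adapter trimming,
    concatemer screening, read condensation); clusters reads across
    samples into putative loci with greedy identity clustering, reference
    mapping and position-based merging; calls genotypes from per-sample
    haplotype read counts under Mendelian ratio thresholds with
    population rescue of provisional heterozygotes, gap-coded indels and
    duplicate-locus screens; and summarises data quality (missingness
    accounting, binomial allele balance, depth variance components, site
    frequency spectra, star-activity locus classification). A bias-aware
    library simulator (length/GC amplification bias, tapered size
    selection, small-fragment carryover, star activity, chimeras, null
    alleles) generates multiplexed FASTQ plus truth tables so the whole
    pipeline is testable on toy genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
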