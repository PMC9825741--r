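Package: oncoreads
Title: Data-Driven Simulation of Tumor and Matched-Control Capture Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds empirical reference models (read depth, base quality,
    position-based systematic error, insert size) from control whole-exome or
    targeted-sequencing alignments over a capture panel, and generates synthetic
    tumor and matched-control FASTQ reads that embed phased germline SNPs and
    clonality-aware allele-specific somatic copy-number alterations and point
    mutations at a chosen tumor content. Includes closed-form allele-dosage
    arithmetic (expected BAF, VAF and log2 ratios), a synthetic fixture
    generator for end-to-end testing, and scenario drivers for tumor-content
    dilution series and longitudinal subclone dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    GenomicRanges,
    GenomeInfoDb,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    Rsamtools,
    S4Vectors,
    stats,
    SummarizedExperiment,
    tibble,
    tidyr,
    utils,
    VariantAnnotation,
    yaml
Suggests:
    GenomicAlignments,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
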