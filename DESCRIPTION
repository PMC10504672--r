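Package: ptascrub
Title: Filtering Amplification Artifacts from PTA-Based Single-Cell Whole
    Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Separates true somatic variants from whole-genome-amplification
    artifacts in single-cell sequencing data produced with primary
    template-directed amplification (PTA). Base substitutions are classified
    by a random forest over 26 genomic features (allelic imbalance of the
    surrounding phased germline heterozygous variants, mutation type, 10-bp
    flanking sequence context, distances to genes and simple repeats,
    transcriptional strand, replication timing), with per-sample cutoff
    calibration from read-backed phasing and 96-channel mutational spectra.
    Indels are filtered by cross-individual recurrence and homopolymer
    context. Copy-number variants, copy-neutral loss of heterozygosity and
    breakend-supported structural variants are called from panel-of-normals
    normalized read depth, deviation-of-allele-frequency profiles of germline
    heterozygous sites, and breakend records. A synthetic-data module
    generates inputs with the statistical structure the method assumes, so
    the full pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    randomForest,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
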