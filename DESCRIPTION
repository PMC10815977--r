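Package: cffrag
Title: Cell-Free DNA Fragmentomics of Gene Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links gene activity inferred from cell-free chromatin
    immunoprecipitation sequencing (cfChIP-seq) enrichment to cell-free DNA
    (cfDNA) fragmentation features: fragment-length distributions and short
    (<150 bp) fragment fractions, in-silico size selection with mutant/wild-type
    bin enrichment, 3-mer fragment end motif (FEM) frequencies with paired
    differential testing and motif-set overlap statistics, nucleosome-relative
    cleavage (core/linker end fractions), and combined length-plus-motif
    metrics across per-subject gene-activity quantiles. Includes a synthetic
    cohort simulator with planted activity-dependent effects so every stage of
    the pipeline is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    rlang,
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    uwot
Suggests:
    Rsamtools,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
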