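Package: dualmark
Title: Bin-Level Analysis of Dual H3K9me3/H3K27me3 Chromatin at piRNA Source Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome binning with k-mer mappability correction, fragment
    quantification with background subtraction, ROC/AUC classification of
    piRNA source loci from histone-mark signal, interval-overlap odds-ratio
    enrichment, and fold-change-based knockdown dependency classification of
    bins and peaks. Includes a synthetic-data generator with a known truth
    table so the whole pipeline can be exercised end-to-end without external
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
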