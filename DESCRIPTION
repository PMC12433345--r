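Package: entropeaks
Title: Entropy-Based Tissue Specificity of ATAC-seq Consensus Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of multi-tissue bulk ATAC-seq. Builds
    fixed-width consensus peak sets from per-sample MACS2 narrowPeak calls
    (summit +/- 75 bp, reproducibility and read-count filters), classifies
    tissue-specific accessible regions with a Shannon-entropy specificity
    index on reads-per-million profiles, tests known transcription-factor
    motifs for enrichment in tissue-specific regions against GC-matched
    genomic background windows with a hypergeometric tail test, and links
    promoter accessibility to gene expression through per-tissue Pearson
    cis correlations with a transcription-factor expression-support filter.
    Ships a deterministic synthetic-data generator that emulates a
    six-tissue by eight-replicate design with planted ground truth
    (tissue-specific loci, motif instances, promoter-expression
    correlations) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
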