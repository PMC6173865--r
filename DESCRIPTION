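Package: trxgtools
Title: Co-Occupancy and CpG-Island Promoter Analysis of Chromatin Signal Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of ChIP-seq, ATAC-seq and DNase-seq signal
    for CpG-island-centric occupancy studies of Trithorax-group (TrxG)
    complexes: 1x normalisation and input subtraction of binned coverage
    tracks, CpG-density profiling, classification of transcription start
    sites by CpG-island status and of genes as housekeeping or
    tissue-specific from RPKM matrices, calling of accessible TSSs and
    putative enhancers from joint ATAC/Pol II thresholds, peak
    colocalisation and multi-set co-occupancy statistics with binomial
    genomic-overlap enrichment, mutual-exclusivity quadrant analysis, and a
    linear variance decomposition of a target ChIP signal in accessible
    chromatin. Includes a seed-deterministic synthetic-epigenome generator
    with planted ground truth so the whole pipeline can be validated
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
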