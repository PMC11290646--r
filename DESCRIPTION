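Package: xrtcr
Title: Strand-Resolved Analysis of Excision-Repair Sequencing and
    Transcription-Coupled Repair
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of excision-repair sequencing (XR-seq)
    for quantifying transcription-coupled repair (TCR) and discovering
    intergenic transcription in C. elegans-like genomes. Provides
    strand-resolved read counting over genes (transcribed versus
    non-transcribed strand), RPKM normalisation, metagene and TSS
    profiles, fixed-width genomic binning with blacklist and gene
    exclusion for intergenic transcription calls, chromatin-state read
    profiling, epigenomic track scoring against random genomic regions,
    and segmented time-course trend detection with permutation-derived
    significance thresholds. A fully parameterised synthetic-data
    generator emulates the sequencing assays (XR-seq dual-incision
    excision geometry at TT dinucleotides, poly(A) RNA-seq, short- and
    long-capped RNA-seq, epigenomic tracks) so that every pipeline stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
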