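Package: seqprofiler
Title: Single-Cell Sequence-to-Profile Modeling with a Cell-Conditioned Decoder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts single-cell RNA coverage and ATAC insertion profiles from
    DNA sequence using a sequence encoder adapted with low-rank (LoRA) modules
    and a hypernetwork that generates a per-cell 1x1 convolutional decoder from
    the cell's embedding. Includes efficient per-cell coverage archives built
    from alignments or fragment files, squashed-scale target transforms,
    training with a joint Poisson-multinomial loss, profile- and gene-level
    evaluation metrics, in silico transcription-factor motif mutation scoring,
    eQTL variant effect prediction with cell-type deconvolution, and a fully
    synthetic multiome generator with known ground truth for end-to-end testing
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
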