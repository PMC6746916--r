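Package: splicebins
Title: Bin-Based Differential Alternative Splicing Analysis for
    Light-Regulated Seed Germination Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects light-regulated changes in alternative splicing and gene
    expression from spliced RNA-seq alignments of Arabidopsis seeds irradiated
    with red or far-red light pulses. Multiexonic genes are partitioned into
    exon, intron and alternatively spliced bins; reads are summarised at gene,
    bin and splice-junction level; differential expression and gene-normalized
    differential bin usage are tested with a negative-binomial exact test;
    candidate bins are confirmed by percent-spliced-in (PSI) and
    percent-intron-retention (PIR) changes computed from junction and
    intron-boundary reads. Downstream helpers cover GO over-representation
    with enrichment factors, splicing-index quantification from RT-PCR band
    densitometry, and germination statistics (angular transform, two-way
    ANOVA with Fisher's LSD). A spliced-read simulator with known ground
    truth exercises the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    car
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
Config/testthat/edition: 3
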