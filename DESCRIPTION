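Package: kinduce
Title: Kinetic Transcriptome Analysis of Cellulase-Producer Strains Under
    Lactose Induction
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested re-usable pipeline for kinetic transcriptome analysis
    of two related Trichoderma reesei cellulase-producer strains induced by
    lactose fed-batch cultivation. Covers probe-level two-channel microarray
    preprocessing (global lowess normalization, background-threshold
    detectability, transcript summarization), moderated empirical-Bayes
    differential-expression selection, consensus K-means clustering of
    strain-by-time expression profiles with co-occurrence aggregation,
    RPKM-based cross-strain basal-expression comparison, mutation-to-gene
    window integration, functional-category reporting, and fed-batch
    productivity arithmetic. A synthetic-data generator with known ground
    truth exercises every stage end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    knitr
Config/testthat/edition: 3
VignetteBuilder: knitr
RoxygenNote: 7.3.3
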