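Package: pafEnhancers
Title: Co-Occupancy and Positional Analysis of Paf1C at Promoters and
    Enhancers
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrative analysis of ChIP-seq peak calls, binned coverage
    tracks and knockdown expression tables around the RNA polymerase
    II-associated factor 1 complex (Paf1C, ChIP target Ctr9) at promoters
    and enhancers: co-occupancy calling by 1-bp interval intersection,
    strand-aware summit-to-TSS offset statistics for pausing factors
    (NELFA, RNAPII Ser5p, Ctr9), NELFA-Ctr9 summit pairing and
    directionality on enhancers, expression-stratified metagene and
    anchored-heatmap profiling with quantile normalization, super-enhancer
    versus typical-enhancer occupancy-density contrasts with rank-sum
    testing and length-matched shuffled controls, knockdown differential
    summaries by enhancer association group, enhancer-RNA containment
    analysis, and combined-mark (H3K27ac + Ctr9) active-enhancer
    prediction. A calibrated synthetic-data generator with a full plant
    map makes every stage testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    BiocGenerics,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    limma,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
biocViews: ChIPSeq, Epigenetics, Coverage, Transcription, Sequencing
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
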