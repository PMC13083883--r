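Package: ythdfpipe
Title: m6A Reader Binding, RNA Decay and Retrotransposon-Linked Polymerase
    Analytics for Early Embryo Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the post-alignment analyses used to
    study how the m6A reader proteins Ythdf1/2/3 degrade methylated transcripts
    (including SINE/B2 retrotransposon RNAs) and thereby shape RNA polymerase II
    transcription in early mouse embryos. Provides CLIP-style read 5'-end
    clustering with summit calling, background enrichment and DRACH motif
    filtering; fractional transposable-element subfamily quantification and
    binding enrichment; median-of-ratios normalisation with stratified
    log2-fold-change and Kolmogorov-Smirnov decay statistics; developmental
    stage-pattern classification against template expression programs; CUT&Tag
    metagene profiles, promoter pausing indices and B2-distance-stratified
    differential signal; and a seeded synthetic-data generator that emulates
    the structure of all of these inputs so every step is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
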