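Package: lncmap
Title: Discovery, Characterisation and Co-Expression Analysis of Long
    Non-Coding RNAs from Multi-Tissue RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested reimplementation of a lncRNA "BodyMap" analysis
    pipeline for a mammalian transcriptome: hierarchical filtering of
    assembled transcripts into high-confidence lncRNAs, positional
    classification (intergenic, antisense, intronic, cis-regulatory),
    RPKM expression summaries, Jensen-Shannon tissue-specificity
    scoring with Z-score tissue association, genome-alignment
    (UCSC chain) and BLAST-hit conservation classification, MA-plot
    random-sampling differential expression between developmental
    stages, weighted co-expression network analysis with module
    eigengenes and guilt-by-association GO inference, and
    hypergeometric enrichment. Ships a synthetic-data generator that
    plants ground truth for every stage so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    rtracklayer,
    Biostrings,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
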