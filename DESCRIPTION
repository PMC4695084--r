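Package: juncspect
Title: Multi-Tissue Splice Junction Discovery, Filtering, and Tissue Specificity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for characterising tissue-restricted alternative
    splicing from multi-tissue RNA-seq alignments. Extracts putative splice
    junctions from spliced SAM alignments, filters them by read-offset
    entropy, average mismatches and minimum intron length, classifies them
    against known intron annotation, quantifies junction and gene expression
    with a cross-tissue library-size normalization, and summarises tissue
    specificity (tissue-count distributions, junction-gene specificity
    matrices, single-end/paired-end concordance, tissue-specific BED12
    tracks). Includes a synthetic multi-tissue alignment generator with
    planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicAlignments,
    Rsamtools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    jsonlite,
    yaml,
    methods,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
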