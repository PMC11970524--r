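Package: regRemodel
Title: Comparative Multi-Omics Analysis of Diapause Regulatory Remodeling
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how vertebrate diapause arose through regulatory
    remodeling of ancient gene duplicates. The package classifies paralog
    pairs by duplication age and diapause expression specialization, tests
    age-bin enrichment by bootstrap subsampling and chi-square contingency
    tests, projects chromatin-accessibility peaks across species through a
    colinear alignment-block map and assigns evolutionary conservation
    categories, scores and scans position weight matrices to assess
    transcription-factor binding-site conservation and mutation- versus
    transposon-derived origin, tests transposable-element family enrichment
    against genome, all-chromatin and shifted control-locus backgrounds,
    quantifies transcriptome program shifts in transcription-factor knockouts,
    and classifies diapause-specific lipids from untargeted lipidomics tables.
    Seeded synthetic-data generators with planted ground truth exercise every
    stage without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    car,
    jsonlite,
    yaml,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
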