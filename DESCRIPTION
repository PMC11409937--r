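Package: barseqfit
Title: Community Fitness Analysis for Randomly Barcoded Transposon Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for RB-TnSeq (random-barcode transposon sequencing)
    fitness experiments run in multi-species communities. Covers insertion-pool
    construction from transposon-junction reads, barcode counting from BarSeq
    amplicon reads, per-gene fitness estimation with smoothed-median and mode
    normalization, moderated t-score effect calling, cross-condition pleiotropy
    classification (e.g. phage-resistance / fungal-sensitivity trade-offs), and
    dilution-plating growth statistics (titers, MOI, efficiency of plaquing,
    Tukey multiple comparisons). Includes a synthetic-community generator that
    produces genomes, barcoded insertion libraries, condition-dependent
    selection outcomes, sequencing reads and plate counts with the statistical
    structure the analysis assumes, so the whole pipeline is testable without
    external sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
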