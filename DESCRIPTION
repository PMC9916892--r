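Package: regvar
Title: Discovery of Putative Regulatory Genomic Variants from Somatic
    Hotspots, CNV Associations and Chromatin Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative pipeline for nominating regulatory genomic
    variants in cancer cohorts. Detects somatic point-mutation hotspot
    windows with a Poisson-binomial recurrence test, discovers
    case-enriched copy-number variant regions (CNVRs) by per-base
    Fisher association with density-based clustering and
    independence-score representative selection, annotates variants
    against a merged multi-source reference gene list, calls
    enhancer-promoter interactions (EPIs) from significant Hi-C contacts
    and H3K27ac peaks, links enhancer-overlapping variants to target
    genes with whole-genome-sequencing replication, and performs
    hypergeometric over-representation analysis of the resulting gene
    lists. Ships a seeded synthetic-fixture generator so every stage can
    be exercised against planted ground truth without external data.
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
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
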