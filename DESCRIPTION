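Package: rrbstage
Title: RRBS Differential Methylation Across Breast Tumor Progression Stages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end reduced representation bisulfite sequencing (RRBS)
    analysis workflow for tracking promoter DNA methylation across stages of
    ductal breast tumor progression (normal, atypical ductal hyperplasia,
    ductal carcinoma in situ, invasive carcinoma). Implements in-silico
    MspI/TaqI double digestion with fragment size selection, a three-letter
    (C-to-T collapsed) bisulfite read aligner with bisulfite-aware mismatch
    counting and a second-best uniqueness rule, per-CpG methylation calling
    with coverage filtering and promoter/gene-body/CpG-island annotation,
    Fisher exact (or Welch t) tests for differential promoter methylation
    against normal tissue, classification of genes into stage-progression
    categories, and direction-concordance scoring against external gene
    expression tables. A fully seeded synthetic-data generator produces
    genomes, stage-specific methylation profiles and directional bisulfite
    reads with exported ground truth so every stage of the pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
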