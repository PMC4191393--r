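Package: mirtail
Title: Calling and Quantifying Non-Templated 3' Nucleotide Additions on
    Mature miRNAs
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying 3' tailing (non-templated mono- and
    oligo-nucleotide addition) of mature microRNAs in small RNA
    sequencing data. Predicts terminal uridylyl transferase (TUTase)
    substrate miRNAs with a bipartite sequence motif (GUAG followed by
    UUGU), matches reads to a mature miRNA reference with deterministic
    5'-anchored alignment, classifies each read's 3' end as genomic
    (WT), untemplated uridylated, adenylated, other, or
    templating-ambiguous, and quantifies condition-dependent shifts
    between uridylation and adenylation with exact enrichment
    statistics. Includes a seeded two-condition read simulator with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
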