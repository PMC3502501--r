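Package: sagedge
Title: Comparative SAGE Tag Extraction, Annotation and Digital
    Differential Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative Serial Analysis of Gene Expression
    (SAGE): parsing of NlaIII-anchored concatemer reads into ditags with
    PCR-duplicate removal, construction of virtual tag-to-gene databases
    from cDNA collections, two-library digital differential-expression
    statistics (Audic-Claverie, Fisher exact and pooled two-proportion
    tests with Benjamini-Hochberg correction), focus-gene selection,
    gene-set intersection with hypergeometric enrichment, and
    cross-species concordance scoring against compartment-resolved human
    expression tables.  Includes a fully specified synthetic-data
    generator with a ground-truth ledger for end-to-end validation, and
    packaged fixtures transcribing the reference mouse kidney SAGE
    library tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
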