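Package: vartoprot
Title: Harmonize Clinical Variants and Translate Them onto Protein Isoforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline toolkit for curating small genetic variants linked to
    monogenic (Mendelian) disease, built around the gene panel workflow used for
    maturity-onset diabetes of the young. Variants reported in three
    heterogeneous source dialects (an Ensembl-style exon-overlap export, a
    ClinVar-style phenotype export, and a literature table) are normalized to a
    common left-aligned VCF-style representation, classified by predicted
    consequence on each transcript, cross-tabulated against clinical
    significance, consolidated into a two-level evidence database with VCF
    output, and translated onto every protein isoform of their genes to produce
    proteogenomic FASTA databases and per-gene variant overlay figures. A
    seeded synthetic-data generator with planted ground truth makes every stage
    testable without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
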