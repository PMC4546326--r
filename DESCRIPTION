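Package: cnvdrive
Title: Integrated Copy-Number and Expression Analysis of CNV-Driven Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrated analysis of somatic copy-number segments and
    tumor/normal expression profiles to identify CNV-driven genes:
    length-binned copy-number burden with a sample-label permutation test,
    gene-level copy-number calling with a case-recurrence / control-absence
    frequency filter, fold-change screening of differentially expressed
    genes, sign-concordance classification of CNV-driven genes, and
    hypergeometric gene-set over-representation analysis. Includes a
    synthetic paired tumor/normal data generator with planted recurrent
    focal events for end-to-end validation, and readers/writers for SEG
    segment files, expression matrices, BED-like gene models, GMT gene
    sets and Circos track files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    S4Vectors,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
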