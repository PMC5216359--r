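Package: its2auth
Title: ITS2 Barcode Library Analysis and Species-Specific PCR-RFLP Assay
    Design for Herbal Authentication
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for authenticating herbal raw materials against a
    reference DNA barcode library. Implements barcode-library statistics
    (haplotype collapsing, variable sites, Kimura 2-parameter distances and
    barcode-gap assessment), neighbor-joining trees with bootstrap support,
    mining of fixed species-diagnostic SNP and indel characters, in-silico
    PCR and restriction-digest prediction with mismatch-engineered primer
    design for species-specific PCR-RFLP assays, and batch identification
    of query sequences with a product-level authentication report. A
    synthetic-data generator produces reference libraries and market-style
    query sets with planted diagnostic characters for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    seqinr,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
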