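Package: itemrisk
Title: Population-Weighted HLA-DRB1 Immunogenicity Risk Assessment for
    Therapeutic Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Matrix-based scanning of therapeutic protein sequences for
    predicted HLA-DRB1-restricted T-cell epitopes, with length-normalized
    epitope-density scores, adjustment for regulatory T-cell epitopes
    (Tregitopes), HLA carrier-frequency aggregation across population
    studies, frequency-weighted score distributions by resampling,
    individual allele-pair (iTEM) scores, detection of allele pairs with
    differential joint carrier probability between populations, and paired
    nonparametric comparison statistics with effect sizes. Ships a
    reference table of HLA-DRB1 carrier frequencies for Japanese and
    Caucasian populations and a synthetic-data generator so the full
    pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
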