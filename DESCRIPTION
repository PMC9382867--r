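Package: varcascade
Title: Family-Based Rare-Variant Filtering Cascades for Exome Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Auditable rare-variant discovery for small families sequenced by
    whole-exome sequencing. Reads multi-sample VCFs and ANNOVAR-style
    annotation tables, decomposes multiallelic sites with per-allele genotype
    recoding, applies quality, consequence-class, population-frequency and
    candidate-gene-panel filters as ordered cascades with per-step survivor
    counts, and encodes carrier-pattern, dominant, recessive-homozygous and
    compound-heterozygous selection rules over affected relatives. Includes
    gene-set (pathway) prioritization with gene-family expansion, CADD
    phred-to-percentile conversion, and a synthetic-data generator that
    plants variants with fully known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
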