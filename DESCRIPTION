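Package: spateqtl
Title: Spatial eQTL Discovery from Restriction-Fragment Chromatin Contacts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps regulatory connections between disease-associated SNPs and
    the genes they physically contact. Performs in-silico restriction
    digestion of a genome (MboI-style GATC sites by default), assigns SNPs to
    restriction fragments, looks up Hi-C fragment-pair contacts on a
    presence/absence basis across cell lines, overlaps partner fragments with
    gene annotations to form non-redundant SNP-gene pairs classified cis or
    trans (1 Mb TSS window), tests each pair for genotype-expression
    association per tissue by linear regression, selects significant eQTLs by
    a stepwise Benjamini-Hochberg procedure with separate trans and per-gene
    cis families, and assesses enrichment of eQTL connections against Monte
    Carlo background SNP sets. Includes a synthetic-data generator with
    planted spatial links and planted eQTL effects so the whole pipeline is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
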