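Package: hlakir
Title: Immunogenetic Data Transformation and Association Analysis for HLA and KIR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms HLA allele calls and KIR gene-content tables into
    biologically meaningful association variables (allele counts at 1- to
    4-field resolution, supertype and G-group counts, per-position amino-acid
    residue counts from protein alignments, heterozygosity, Grantham
    evolutionary divergence over the peptide-binding region or its B and F
    pockets, Bw4/Bw6/C1/C2 NK-ligand groups, KIR gene presence and validated
    HLA-KIR interactions) and provides a statistical association engine with
    per-variable placeholder substitution into linear, logistic or Cox models,
    Hardy-Weinberg testing, frequency filtering, genetic inheritance
    encodings, omnibus likelihood-ratio tests over grouped variables,
    stepwise conditional search for independent signals, and multiple-testing
    correction. A seeded synthetic-data module generates genotypes,
    alignments and phenotypes for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
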