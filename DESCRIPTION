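Package: scqtlmap
Title: Single-Cell cis-eQTL Mapping with Zero-Inflated Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joins a genes-by-cells expression matrix with a per-cell SNP
    genotype matrix and maps cis expression quantitative trait loci (eQTLs)
    at single-cell resolution. Provides five expression normalization
    methods, joint gene- and SNP-level quality-control filtering, window-based
    cis SNP-gene pairing from genomic annotations, association testing per
    cell group under linear, Poisson, or zero-inflated negative binomial
    (ZINB) likelihood-ratio models with multiple-testing correction, and
    genotype-stratified visualization. Includes a synthetic-data generator
    with known ground truth and a command-line pipeline entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    patchwork,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    methods,
    tidyr,
    utils,
    yaml
Suggests:
    BiocGenerics,
    GenomeInfoDb,
    S4Vectors,
    DESeq2,
    limma,
    rtracklayer,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
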