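Package: linepopgen
Title: Population Genomics of LINE Insertion Polymorphisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the population-genomic analysis of polymorphic LINE
    (long interspersed nuclear element) insertions alongside SNPs in two
    populations of the green anole. Reads and filters multi-sample SNP and
    mobile-element-insertion (MEI) VCFs, computes site frequency spectra,
    Tajima's D, Weir-Cockerham F_ST and allele-sharing partitions, classifies
    insertions as complete or truncated, simulates the structured coalescent
    under a two-population isolation-with-migration model with population
    size changes, fits demographic parameters to the joint site frequency
    spectrum by simulation-based composite likelihood with parametric
    bootstrap confidence intervals, and tests whether insertion frequency
    spectra deviate from neutral expectations using simulation-based
    empirical p-values. A synthetic-data generator produces complete input
    bundles (SNP VCF, per-family MEI VCFs, population map) with realistic
    clade-specific truncation-length distributions and optional purifying
    selection, so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
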