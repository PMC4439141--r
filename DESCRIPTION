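Package: stressgene
Title: Gene-Based Association Tests for Multiple Correlated Diurnal Cortisol Features
Version: 0.1.0
Authors@R: person("MESA", "Methods", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Candidate-gene association testing for multiple correlated
    phenotypes, built around features of the diurnal cortisol curve. Implements
    four analytic strategies: per-SNP Wald tests of single features, the
    MultiPhen reverse proportional-odds joint test, the SKAT variance-component
    score test per gene and feature with an exact mixture-of-chi-squares null,
    and a gene-level multi-phenotype test that combines per-feature SKAT
    p-values by Fisher's method and calibrates the combined statistic with a
    genotype-permutation null that preserves the phenotype correlation
    structure. Includes cross-stratum p-value meta-analysis (weighted Z,
    Fisher, weighted Fisher), diurnal cortisol feature construction from
    salivary diary records, and a synthetic-data generator emulating
    LD-structured common-variant genotypes and correlated phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    S4Vectors,
    GenomicRanges,
    SummarizedExperiment
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
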