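Package: captivepop
Title: Inbreeding, Drift, and Selection in Captive Breeding Programs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward-in-time simulation and genomic analysis of captive
    breeding colonies managed under mean-kinship minimization, random
    mating, or trait-based (docility) breeder selection.  Provides
    pedigree kinship and inbreeding coefficients with a gene-dropping
    Monte Carlo cross-check, a simulation-based neutrality test that
    flags SNPs whose allele-frequency change is inconsistent with drift
    under the matched breeding protocol, D'-based linkage grouping of
    unphased biallelic genotypes, resampled multilocus heterozygosity,
    effective population size from heterozygosity loss, and
    permutation-tested heterozygosity-fitness correlations.  A synthetic
    colony generator produces complete study inputs (genotypes with
    block linkage structure, pedigrees, fitness traits with inbreeding
    depression) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    SummarizedExperiment
Config/testthat/edition: 3
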