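Package: admixisle
Title: Simulation and Inference of Sex-Biased, Assortative Admixture Histories
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time simulation of two-source admixed populations with
    sex-specific migrant contributions each generation, ancestry-assortative
    mating, autosome and X-chromosome transmission, and founder-segment
    tracking, together with the matching inference stages: admixture dating
    from the decay of local ancestry disequilibrium in genomic windows, a
    permutation test for ancestry-assortative mating built on phased parental
    haplotypes, grid inference of sex-biased source contributions from X
    versus autosomal ancestry, run-of-homozygosity length classification with
    ancestry-switch statistics, and identity-by-descent segment totals,
    networks and a kinship proxy. An end-to-end pipeline turns a simulated or
    user-supplied local-ancestry dataset into the full result set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
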