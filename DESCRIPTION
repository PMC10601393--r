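Package: msatabc
Title: Coalescent Simulation and Random-Forest ABC for Microsatellite Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for demographic inference from
    diploid microsatellite (SSR) genotypes. Simulates genotype datasets under
    competing divergence/admixture scenarios with a backward-time coalescent
    and a generalized stepwise mutation model, summarizes them with the
    standard one-, two- and three-population microsatellite statistic battery
    (130 features for five populations), and performs approximate Bayesian
    computation with random forests: scenario choice by classification forest
    (votes, posterior probability, out-of-bag prior and local error rates) and
    parameter estimation by quantile regression forests with partial least
    squares components. Also provides the classical diversity and
    differentiation layer: allelic richness by rarefaction, unbiased expected
    heterozygosity, Weir-Cockerham F-statistics, maximum-likelihood null
    allele frequencies, null-allele-corrected F_ST with bootstrap confidence
    intervals, and permutation tests for group contrasts, with Genepop
    import/export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    generics,
    ggplot2,
    ranger,
    MASS,
    mixOmics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
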