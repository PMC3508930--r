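Package: ystrata
Title: Population Structure Analyses for Y-Chromosomal Haplogroup and STR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses of male-lineage population structure from Y-chromosomal
    haplogroup counts and 17-locus Y-STR haplotypes: Nei gene diversity and
    lineage-class proportions, Fisher exact enrichment tests at the population
    and group level, hierarchical AMOVA with permutation tests and a multinomial
    bootstrap for comparing alternative population groupings, R_ST distances,
    covariance PCA and non-metric MDS ordination, reduced-median haplotype
    networks, haplogroup age estimation from STR repeat variance under the
    effective-mutation-rate calibration, and a coalescent Markov chain Monte
    Carlo sampler for population split times under the single-step stepwise
    mutation model, with admixture-sensitivity scenario simulations. Ships a
    curated haplogroup count matrix for 31 endogamous populations from Tamil
    Nadu together with a structured-coalescent synthetic data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
LinkingTo:
    Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
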