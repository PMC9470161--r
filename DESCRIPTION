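Package: rhizotrait
Title: Quantitative Genetics of Rhizosphere Microbiome Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Treats the abundance of rhizosphere microbial groups as
    quantitative traits of the host plant and carries an amplicon (ASV)
    count table with a field design, a SNP panel, and plant phenotypes
    through a full quantitative-genetics workflow: community ordination
    and PERMANOVA, construction of log relative-abundance rhizobiome
    traits, repeatability-style heritability with a permutation null,
    mixed-model BLUPs, Lande-Arnold selection differentials from a
    smoothed fitness function with bootstrap significance, a BayesS
    spike-slab sampler for the MAF-effect-size coupling parameter S,
    mixed-model (EMMAX/P3D) GWAS with effective-SNP Bonferroni
    thresholds, microbe-associated plant locus (MAPL) hotspot windows
    with gene annotation, and microbe-phenotype integration. A seeded
    synthetic-data generator emulates the field study so every stage is
    verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    mgcv,
    lme4,
    ape,
    vegan,
    vcfR,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phyloseq,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
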