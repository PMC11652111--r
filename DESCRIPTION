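Package: elevdiv
Title: Elevational Gradients of Taxonomic and Phylogenetic Plant Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for elevational-gradient diversity
    analysis of mountain floras: cleaning of occurrence records, binning into
    fixed-width (100 m) elevational belts, taxonomic and phylogenetic
    alpha-diversity (species richness, Faith's PD, phylogenetic endemism),
    Jaccard and Cody beta-diversity between adjacent belts, the net
    relatedness index (NRI) under randomization null models, and the
    gradient and determinant regressions (quasi-Poisson GLMs, native versus
    non-native richness correlation, diversity-peak determinants). Includes a
    synthetic-data module that simulates phylogenies, elevational ranges,
    occurrence records with realistic cleaning hazards, belt-area profiles
    and non-native subsets, so the whole pipeline is testable without
    herbarium downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
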