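Package: minepop
Title: Parallel Colonization Genomics: Forward Simulation, Isolation by
    Distance, and Differentiation Scans for Mine-Coast Population Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for testing single versus multiple origins of derived
    populations that have colonized patchy, novel habitats (such as
    metal-contaminated mine spoils) from a widespread ancestral habitat.
    Provides a forward-in-time diploid Wright-Fisher colonization simulator
    with stepping-stone demography and an isolation-by-distance contrast
    that discriminates independent from single colonization origins;
    Weir-Cockerham FST variance components, nucleotide diversity, windowed
    Tajima's D and genotypic LD pruning; f4 quartet admixture tests with
    block-jackknife z-scores; FST outlier scans with an exact multi-set
    intersection test; and a hierarchical Balding-Nichols genotype
    generator with planted selection outliers for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    geosphere,
    ape,
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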