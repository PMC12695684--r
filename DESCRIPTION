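Package: rootgroups
Title: Root-Architecture Group Analysis for Augmented Block Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying plant genotypes into nine root-architecture
    groups from seedling phenotyping experiments laid out as augmented block
    designs. Computes derived root traits (specific root length, root length
    density, root tissue density and relatives) and spectrophotometric
    chlorophyll and carotenoid concentrations, removes block effects from
    unreplicated test genotypes using replicated checks, classifies genotypes
    into depth and density classes by the 95 percent confidence interval of
    the trait mean, and provides the downstream group statistics: one-way and
    factorial ANOVA, LSD mean comparison, canonical discriminant analysis,
    Pearson trait correlations and Ward hierarchical clustering. A synthetic
    data generator emulating the experimental design supports testing and
    parameter-recovery benchmarks.
License: MIT
Encoding: UTF-8
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
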