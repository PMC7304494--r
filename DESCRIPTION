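Package: popstructr
Title: Population Structure, Admixture, and Allele-Frequency Divergence from Genotype Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for population-structure analysis of diploid
    biallelic genotype data: variant quality control (missingness, minor allele
    frequency, exact Hardy-Weinberg test, windowed LD pruning), identity-by-state
    distances, principal component analysis of standardized genotypes, supervised
    admixture estimation by expectation-maximization against reference-panel
    allele frequencies, UPGMA and neighbor-joining trees, resampled population
    stratification statistics (heterogeneity, separation, compactness),
    Weir-Cockerham FST, three-level AMOVA with Slatkin linearized distances, and
    a cross-panel allele-frequency Z-score screen. Includes a synthetic-cohort
    generator with known ground truth (Balding-Nichols divergence, Dirichlet
    admixture) so every stage is testable without controlled-access data, and
    ggplot2 visualizations including admixture-informed PCA pie plots and
    dendrogram-ordered admixture bar plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    grDevices,
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
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
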