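Package: ftmsflow
Title: Downstream Analysis of Direct-Injection FT-ICR MS Metabolomic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for the downstream analysis of direct-injection
    FT-ICR mass-spectrometry metabolomic data after molecular formula
    assignment. Reads Formularity-style report tables, filters peaks by
    mass window, carbon-13 isotopologue presence, assignment error and
    sample presence, computes thermodynamic and molecular indices (NOSC,
    Gibbs free energy of carbon oxidation, modified aromaticity index,
    double-bond equivalents), assigns van Krevelen compound classes,
    normalizes intensities with a bias-scoring procedure to choose among
    normalization methods, and provides diagnostics, group comparisons,
    chemodiversity indices (Shannon, Gini-Simpson, Chao1, Rao's quadratic
    entropy), multivariate statistics (distance matrices, PERMANOVA, NMDS,
    PCA) and ab initio mass-difference transformation networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    cluster,
    dplyr,
    ggplot2,
    igraph,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
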