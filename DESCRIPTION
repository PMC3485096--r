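Package: firecomm
Title: Pairwise Community Phylogenetics of Fire-Response Guilds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies co-occurrence of plant species pairs across nested
    vegetation plots with Schoener's index, relates co-occurrence to
    phylogenetic, phenotypic and edaphic distances via exact quantile
    regression with species-level permutation tests and bootstrap
    confidence intervals, and characterises phylogenetic signal in
    continuous traits (Pagel's lambda), binary traits (the D statistic)
    and node-age divergence patterns (independent contrasts with a
    kappa branch-length transformation). Includes a synthetic-data
    generator for nested survey designs with two fire-response guilds,
    soil gradients, geographic ranges, and a tunable guild-specific
    co-occurrence repulsion mechanism, so the whole pipeline can be
    validated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    picante,
    quantreg,
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
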