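Package: clonescape
Title: Spatial Clonal Structure Analysis of Partially Clonal Plant Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the spatial clonal structure of partially
    clonal plant populations genotyped at codominant microsatellite loci.
    Resolves sampled ramets into multilocus genotypes and lineages with
    Pgen/Psex confidence measures (round-robin allele frequencies), computes
    clone-censored per-locus diversity statistics and population-level clonal
    diversity (genotypic richness, Pareto clone-size slope, Shannon-Wiener
    equitability, clonal subrange), tests spatial aggregation of clonemates and
    Loiselle kinship autocorrelation at ramet and genet level with permutation
    envelopes, estimates per-genet occupied areas from convex hulls and
    constant-area buffer polygons with overlap accounting, derives per-patch
    genotypic indices (richness, equitability, spatial mixing) and their
    regressions on patch area, and simulates spatially explicit clonal
    populations (phalanx or guerrilla architecture) sampled on a 1-m grid so
    every stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    grDevices,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
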