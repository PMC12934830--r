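Package: logddg
Title: Diversity-Dependent Geographic Diversification: Simulation,
    Equilibrium Theory and Tree Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative simulation of phylogenies with evolving geographic
    ranges under a logarithmic diversity-dependent GeoSSE birth-death process,
    in which local species richness modulates per-lineage rates of extinction,
    within-region speciation, dispersal and between-region (allopatric)
    speciation. Provides the local equilibrium-diversity theory for the
    process (balance equation, numerical root, closed form and self-consistent
    fixed point), a tree-shape statistic suite (Aldous beta, Pybus-Harvey
    gamma, treeness, mean range size) with grid-study drivers, and a
    training-dataset generator for likelihood-free inference that writes
    Newick trees, one-hot tip-range tables and parameter labels.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
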