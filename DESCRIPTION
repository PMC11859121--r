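Package: parsocial
Title: Evolutionary Simulation of Parochial (Similarity-Biased) Social Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based evolutionary simulations of social learning in
    populations divided into two intermixed groups with distinct adaptive
    optima in continuous two-dimensional trait space. Agents carry heritable
    reliance on social learning, parochialism (the probability of excluding
    learning targets that do not share their identity marker), and a social
    learning strategy (unbiased, conformist, or pay-off-biased transmission);
    traits evolve under pay-off-proportional reproduction with mutation and a
    Gaussian fitness function. Provides a fast compiled simulation core, a
    pure-R reference implementation of every model primitive, experiment
    presets covering the principal result regimes (selection for social
    learning under error-prone individual learning, its collapse in diverse
    populations, the parochial rescue, majority/minority asymmetry, and
    competition among learning strategies), a parameter-sweep runner with
    reproducible seeding, tidy result tables, and plotting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ggplot2,
    rlang,
    parallel,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
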