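Package: exprsel
Title: Selection on Protein Expression Levels in Simple Cellular Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the fitness cost of expressing a protein away from
    its optimal level in a family of coarse-grained cellular models: a
    saturating cost-benefit form derived from a linear metabolic pathway, a
    two-step reversible Michaelis-Menten pathway with an optional
    intermediate-dilution cost, a 20-amino-acid proteome-allocation growth
    model, and a log-linear metabolic control analysis approximation.
    Provides closed-form and numerical optima, exact and small-change
    selection coefficients, seeded random-parameter generators, sweep and
    reporting pipelines returning tidy tables, and population-genetic
    helpers (Ne*s products, mutation-selection balance, gene-maintenance
    thresholds) for interpreting the selection coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    purrr,
    rlang,
    tidyr,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
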