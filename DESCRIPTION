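Package: morphconv
Title: Regime-Dependent Trait Evolution and Morphological Convergence on
    Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for asking whether lineages that share a
    derived ecology converge morphologically. Fits Mk models to discrete
    foraging regimes and draws stochastic character maps, performs
    phylogenetic size correction and allometric slope tests, fits
    single- and multi-regime Brownian motion and Ornstein-Uhlenbeck
    trait models on regime-painted trees with AICc model averaging over
    a 95 percent confidence set, runs phylogenetic principal component
    analysis with maximum-likelihood Pagel's lambda, and quantifies
    convergence of a focal tip set with the distance-based C1-C4 metrics
    under Brownian-motion or multivariate Ornstein-Uhlenbeck ancestral
    reconstructions, judged against a Brownian simulation null. A
    synthetic-data module generates trees, regime histories, and traits
    with known parameters so every stage is testable against truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    phytools,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    nlme,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
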