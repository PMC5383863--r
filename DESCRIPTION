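Package: pggalloc
Title: Public Goods Games with Payoff-Driven Resource Allocation on Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulator for networked public goods games in which
    cooperators redistribute their per-round capital across the games they
    play according to the payoffs each game returned in the previous round,
    via an exponential (softmax) weighting with intensity alpha. Provides
    scale-free substrate generation through the uncorrelated configuration
    model, three synchronous strategy-update rules (normalized replicator,
    unconditional imitation, Fermi), ensemble orchestration with seeded
    reproducibility, and analysis of the emergent observables: cooperation
    levels, bimodal investment-share distributions, degree-resolved wealth
    production, Pareto-style wealth concentration, and the decomposition of
    links into positive and negative participations with backbone metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
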