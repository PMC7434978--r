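Package: beeswitch
Title: Sequential-Choice Strategy Analysis for Bumblebee Foraging Bouts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of sequential choices made by bumblebees
    foraging in a six-disc relative-size discrimination arena. Provides an
    agent-based generator of foraging bouts (random, rule-following,
    win-stay/lose-switch, proximity and hybrid strategies, with within-bout
    reward depletion), block-wise accuracy and conditional-probability
    metrics with enumerated chance levels, a stopped Markov-chain model of
    per-bout performance, spatial landing analysis, and an exact
    nonparametric inference layer (sign-flip enumerated Wilcoxon signed-rank
    and permutation Spearman tests) used to detect strategy switches across
    training blocks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
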