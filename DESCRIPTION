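Package: bdmvalue
Title: Subjective Reward Value from BDM Auction Bids and Dopamine Population Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying trial-by-trial subjective reward value elicited
    with the Becker-DeGroot-Marschak (BDM) second-price auction and its encoding
    by midbrain dopamine neurons. Provides the auction payoff analytics
    (incentive compatibility, optimal bidding), generators for synthetic bidding
    sessions with coherent latent value drift and trial-history effects,
    inhomogeneous-Poisson spike-train generators for two-component dopamine cue
    responses driven by bid-derived reward prediction errors, behavioral
    statistics (rank-order checks, cross-validated lasso variable selection,
    mixed-effects models, bid-coherence analysis), spike-response analysis
    (analysis-window detection from peri-stimulus histograms, neuron
    classification, bid regressions, matched-bid magnitude tests, movement
    controls), and pseudo-population support-vector-regression decoding of bids
    with neuron-dropping curves and shuffle nulls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    lme4,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
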