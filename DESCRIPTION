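Package: beamcea
Title: Within-Trial Cost-Utility Analysis for Two-Arm Randomized Trials
Version: 0.1.0
Authors@R:
    person("Beam", "CEA Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for within-trial evaluation of a two-arm randomized
    controlled trial with a six-month horizon: intention-to-treat outcome
    analysis (last-observation-carried-forward, multiple imputation with
    Rubin pooling, baseline- and age-adjusted ANCOVA), construction of
    quality-adjusted life years by area under the utility curve and of
    per-participant costs from a windowed cost ledger, a Bayesian bivariate
    Gamma model for incremental costs and effects fitted by Markov chain
    Monte Carlo with ICER, cost-effectiveness acceptability curve, net
    monetary benefit and cost-effectiveness plane outputs, and the
    change-score sample-size and power machinery used to design such
    trials. A synthetic-trial generator reproduces the statistical
    structure of the target trial so the full pipeline is testable without
    access to participant-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
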