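Package: clusterMRT
Title: Design, Simulation and Causal Analysis of Cluster Micro-Randomized
    Trials of Gamified Team Competition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for cluster micro-randomized trials (MRTs) in mobile
    health, modelled on a 12-week trial of gamified team competition among
    medical interns.  Provides a synthetic cohort generator with known
    causal structure (teams of interns, daily step, sleep and mood streams,
    missing-at-random missingness and dropout), the weekly three-factor
    team randomization scheme (competition coin, opponent-pairing rule,
    competition-type coin, with the odd-leftover rule), team-week
    aggregation, multiple imputation by chained predictive mean matching
    pooled by Rubin's rules, two-step post-stratification raking weights,
    and a weighted-and-centered least squares (WCLS) estimator of proximal
    causal excursion effects with cluster-robust sandwich variance,
    time-varying and pairing moderation, linear probability models for
    participation, and spline/complete-case sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    splines,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
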