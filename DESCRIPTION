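Package: crowdaniso
Title: Simulation and Analysis of Training-Induced Changes in Visual
    Crowding Anisotropy
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate and analyse a perceptual-learning study of
    visual crowding. Generates four-alternative forced-choice (4AFC) trial
    tables under a cumulative-normal psychometric model and ROI-averaged
    blood-oxygenation-level-dependent (BOLD) time series under a block
    design with a gamma-variate hemodynamic response function. Fits
    psychometric functions by maximum likelihood to recover 68%-criterion
    critical spacings, estimates a general linear model on BOLD runs to
    extract per-condition percent signal change, computes radial-tangential
    anisotropy indices for behaviour and BOLD, and runs the group-level
    inferential battery (paired t-tests, repeated-measures ANOVA, Spearman
    rank correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
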