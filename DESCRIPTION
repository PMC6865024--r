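Package: eibscale
Title: Absolute Versus Relative Scale for Treatment Effects on
    Exercise-Induced FEV1 Decline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deciding whether a continuous treatment effect is
    better described on the absolute scale (a uniform percentage-point
    shift) or on the relative scale (a proportional reduction), using
    individual-participant data from placebo-controlled cross-over trials
    of exercise-induced bronchoconstriction. Provides participant-level
    effect statistics and stratified ratio confidence intervals, linear
    mixed-effects comparisons of intercept-only, intercept-plus-slope and
    slope-only models with clustering by study and drug, regression-to-
    the-mean diagnostics based on the Blomqvist attenuation formula,
    through-origin quantile-regression summaries, DerSimonian-Laird
    random-effects meta-analysis on both scales with Q and I-squared
    heterogeneity statistics, and a synthetic cross-over cohort generator
    for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    optparse
Config/testthat/edition: 3
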