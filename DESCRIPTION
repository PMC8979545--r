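Package: segtraj
Title: Longitudinal Brain System Segregation Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how the modular organization of resting-state
    functional brain networks changes over adulthood and what those changes
    foretell clinically. Builds censored, Fisher-z, negative-truncated
    connectivity matrices from node time series and head-motion traces;
    computes the brain system segregation statistic (the difference between
    mean within-system and mean between-system connectivity as a proportion
    of mean within-system connectivity); fits longitudinal linear
    mixed-effects models of segregation trajectories with education-by-age
    moderation, simple-slope and Johnson-Neyman probing; tests block-level
    connectivity change against a permutation null with FDR control; relates
    within-person segregation change to later dementia severity (CDR sum of
    boxes); and simulates a longitudinal cohort with planted trajectory
    effects for validation and power work.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
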