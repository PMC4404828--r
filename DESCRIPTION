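Package: mcsfr
Title: Multivariate Behavioral Profiling for Concentric Square Field and
    Ethogram Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multi-zone arena exploration tests and
    ethogram-based behavioral assays in rodents. Extracts zone-visit events
    from tracking logs, computes descriptive parameters (latency, frequency,
    duration, distance, velocity), behavioral indexes and rank-based trend
    analysis over functional categories, scores ethogram bout logs into
    coping-style and social-behavior category scores, and applies a
    non-parametric statistical battery with PCA and PLS-DA group profiling.
    Includes a semi-Markov behavior simulator for generating synthetic
    cohorts with known group structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse
Config/testthat/edition: 3
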