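Package: braingender
Title: Brain Gender Continuum Analysis of Functional Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying sex differences in resting-state functional
    connectivity across the lifespan and for placing individual connectomes on
    a continuous female/male ("brain gender") axis. Implements effect-size
    mapping of sex differences at the edge, network, nodal and global levels
    with covariate adjustment and bootstrap intervals; spline trajectories of
    global connectivity with age; a linear support-vector classifier over all
    edges with cubic age residualization and sigmoid (Platt) posterior
    calibration that defines a continuum score in [0,1]; sensitivity
    experiments (sample size, age composition, network ablation, top-weight
    enrichment, atlas concordance); and U-shape tests of the score against
    internalizing symptoms using family-aware exchangeability-block
    permutations with Benjamini-Hochberg correction. A synthetic cohort
    generator with planted, age-dependent sex effects makes the full pipeline
    testable without access-restricted imaging cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pROC
Config/testthat/edition: 3
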