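Package: grouptrax
Title: Trajectory Analysis of Social Behavior in Group-Housed Rodents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how individual behavioral traits relate to
    social relationship formation in small groups of laboratory rodents.
    Provides an agent-based simulator of group cage trajectories with known
    ground-truth social structure, post-processing of multi-animal tracking
    output (speed gating, identity-swap resolution, bounded gap
    interpolation), extraction of standard behavioral-test indices (open
    field, novel object, three-chamber, elevated plus maze, glove test),
    dyadic social interaction metrics (proximity, isolation, approach and
    avoidance events with mover attribution), and the statistical battery
    used in animal-personality work: correlation-matrix PCA with
    salient-loading assignment, ICC(3,k) consistency classification,
    random-intercept mixed-model likelihood-ratio tests, and Fisher-z
    correlation panels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    SummarizedExperiment,
    S4Vectors,
    Rcpp,
    lme4,
    zoo,
    data.table,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'grouptrax-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'TrajectorySet-methods.R'
    'synthetic-arena.R'
    'track-repair.R'
    'behavioral-tests.R'
    'social-metrics.R'
    'stats-suite.R'
    'pipeline.R'
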