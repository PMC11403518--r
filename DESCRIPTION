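Package: dynstates
Title: Dynamic Functional-Connectivity Brain-State Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Sliding-window dynamic functional-connectivity analysis of ROI
    time series: per-window correlation matrices and positive graph strength,
    control-referenced z-scoring, modularity-based data reduction, Ward
    hierarchical clustering with Sarle's cubic clustering criterion to identify
    recurring brain states, motion-aware state selection (motion clusters,
    motion windows, subject exclusion), dwell times, representative windows and
    state hubs, plus the accompanying inferential layer (Welch t-tests,
    one-tailed tie-corrected Kendall tau-b, Benjamini-Hochberg FDR) and
    structural network-composite volumetrics. Includes a synthetic-cohort
    generator with latent state-switching covariance, planted group effects and
    motion artifacts for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'dynstates-package.R'
    'graph-metrics.R'
    'io.R'
    'pipeline.R'
    'state-characterization.R'
    'state-clustering.R'
    'stats.R'
    'utils.R'
    'synthetic.R'
    'volumetrics.R'
    'windowing.R'
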