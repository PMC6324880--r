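Package: wmaconn
Title: Normative Connectome-Based Prediction of Working Memory Ability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for normative modelling of working memory ability (WMA)
    from network-level resting-state functional connectivity (FC). Implements
    the full pipeline: extraction of 171 within- and between-network FC
    features from realigned voxel time series (framewise-displacement
    scrubbing, nuisance regression, optional band-pass filtering, test-retest
    ICC), estimation of individual WMA as the plateau of an inverse learning
    curve fitted to per-session 3-back d-prime, sparse Bayesian (automatic
    relevance determination) linear regression mapping FC to WMA with
    leave-one-out cross-validation and per-connection contribution ratios,
    confound-controlled generalization statistics (partial correlations with
    label-permutation nulls, Hedges' g effect sizes, one-way ANOVA with Holm
    post-hoc tests), and decomposition of predicted group-level impairment
    into per-connection D- and Z-scores with permutation two-way ANOVA,
    Kruskal-Wallis screening and cluster-level summaries. A synthetic-cohort
    generator with planted ground truth supports end-to-end validation
    without access to restricted neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
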