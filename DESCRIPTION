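Package: darrmeta
Title: Multilevel Phylogenetic Meta-Analysis of Developmental Thermal Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for meta-analysing developmental plasticity in ectotherm
    heat tolerance with the developmental acclimation response ratio (dARR)
    as effect size. Computes dARR and its sampling variance from group-level
    summaries (including stepwise multi-temperature comparisons, shared-cohort
    corrections, within-study standard-deviation imputation and thermal
    death time curve conversion), builds phylogenetic correlation and
    shared-treatment sampling variance-covariance matrices, fits multilevel
    heteroscedastic random-effects models by restricted maximum likelihood
    with t-based inference, heterogeneity (I-squared) decomposition,
    prediction intervals, post-stratified marginal means and contrasts, and
    provides a publication-bias and sensitivity suite (small-study and
    time-lag meta-regressions, leave-one-out, subset and cutoff refits,
    funnel data export). A synthetic-data generator with known truth makes
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
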