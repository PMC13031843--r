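Package: cortexcomm
Title: Multi-Region Cortical Population Analysis of Short-Term Memory Robustness
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analyzing trial-structured multi-region calcium-imaging
    population recordings from delayed-response tasks with mid-delay
    distractors. Provides single-neuron epoch and trial-type selectivity
    statistics, three functional-interaction metrics (inter-trial-interval
    pairwise correlation, trial-by-trial correlation, cross-validated ridge
    population prediction), reduced-rank-regression communication subspaces
    with principal-angle similarity, spatial and temporal degeneracy measures
    and predictive-dimension ablation, a FORCE-trained recurrent-network
    attractor simulator with distractor-perturbation and connectivity-ablation
    experiments, a pseudo-mouse population decoding pipeline with a pluggable
    embedding backend, one-tailed bootstrap and Benjamini-Hochberg resampling
    statistics, and a seeded synthetic-cohort generator emulating a control
    and a reduced-connectivity genotype-like cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    rhdf5,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
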