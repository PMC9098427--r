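Package: ptenet
Title: Directed Phase-Transfer-Entropy Networks and Multilayer Task-State Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-trial directed functional connectivity via phase transfer
    entropy (histogram plug-in estimator on Hilbert phases with the Nason-Scott
    bin rule), permutation-based network contrasts between task conditions with
    false-discovery-rate control, and multilayer task-state graphs assembled from
    cross-condition edge-to-edge correlations ("multilinks"). Includes a
    delayed-coupling phase-oscillator generator with planted directed edges and
    trial-level co-modulation for validation, a multifeatured statistical-learning
    stimulus-stream builder with two-alternative forced-choice test construction,
    and the matching behavioral analysis (logit transform, chance-level tests,
    mixed ANOVA, Hedges' g).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    withr,
    ggplot2,
    generics,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
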