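Package: judonet
Title: Correlation-Network Analysis of Judo Match Performance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds significance-filtered Spearman correlation networks over a
    fixed 52-parameter catalog of judo match performance measures (athlete
    profile, anthropometric, inspiratory, physiological, psychophysiological
    and technical-tactical), computes Degree and PageRank centrality with
    tie-aware top-k ranking, and compares network connectivity across three
    inspiratory-muscle pre-activation scenarios (CON, IMPA15, IMPA40).
    Includes a segment-based match and physiological-recovery simulator with a
    planted latent-factor correlation structure, the derived performance
    metrics (effectiveness, efficiency, time-motion summaries, delta and
    rate-of-decay statistics), and nonparametric statistics (tie-corrected
    Spearman with exact permutation or t-approximation p-values, Friedman test
    with Bonferroni-corrected Wilcoxon post-hoc).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
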