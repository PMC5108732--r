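Package: prefrank
Title: Priority Weighting and Ranking-Method Comparison for Preference Elicitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-criteria priority measurement in health services
    research. Implements the Analytic Hierarchy Process (AHP) on a criteria
    hierarchy: reciprocal Saaty-scale judgment matrices, principal-eigenvector
    priority weights by power iteration, consistency-ratio screening, and
    group aggregation of individual judgments (AIJ) or individual priorities
    (AIP) by geometric mean, arithmetic mean, or median. Also provides
    best-worst scaling (BWS Case 1) count analysis with per-block unit
    rescaling, ranking-card ingestion and aggregation, tie-adjusted Kendall
    tau-b rank concordance, BCa bootstrap confidence intervals for group
    weights with interval-overlap rank-stability reports, and a synthetic
    respondent generator (Dirichlet preference heterogeneity, log-normal
    judgment noise on the Saaty grid, Gumbel random-utility choices) so the
    full pipeline can be exercised and validated without survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    boot,
    optparse
Config/testthat/edition: 3
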