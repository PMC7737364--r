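Package: cs1decision
Title: Decision Analysis of Surveillance Versus Risk-Adapted Treatment in
    Pediatric Stage I Testicular Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision-tree model comparing active surveillance with
    risk-adapted treatment for clinical stage I pediatric testicular germ
    cell tumors, using toxicity-weighted chemotherapy cycles as the payoff.
    Provides a small chance/terminal decision-tree engine with expected-value
    rollback and a JSON tree schema, closed-form expected-exposure
    expressions used as an analytic oracle, one-way and two-way deterministic
    sensitivity analyses with exact preference thresholds, aggregation of
    visual-analog-scale toxicity elicitation surveys, and synthetic-data
    generators (simulated surveys and Monte-Carlo patient cohorts) that
    cross-check the analytic results by microsimulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
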