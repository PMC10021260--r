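Package: oxicea
Title: Trial-Based Cost-Effectiveness Analysis of Pulse Oximetry Added
    to IMCI for Diagnosing Severe Childhood Pneumonia
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Micro-costing and decision-analytic modelling toolkit for a
    two-arm cluster-randomized diagnostic trial comparing the WHO
    Integrated Management of Childhood Illness (IMCI) guideline alone
    against IMCI combined with pulse oximetry for diagnosing severe
    childhood pneumonia.  Provides capital-cost annuitization, itemized
    provider and patient cost ledgers, a probabilistic decision tree
    with expected-value rollback and incremental cost-effectiveness
    ratios, one-way (tornado) deterministic sensitivity analysis,
    Monte Carlo probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves and net monetary benefit,
    method-of-moments gamma and beta parameter fitting, and a
    patient-level synthetic trial generator so the whole pipeline runs
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tibble,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
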