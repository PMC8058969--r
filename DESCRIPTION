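Package: markovcea
Title: Markov Cohort Cost-Effectiveness Analysis of TAS-102 Regimens in
    Metastatic Colorectal Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discrete-time Markov cohort modelling for cost-effectiveness
    analysis of chemotherapy regimens, built around a five-state
    (stable disease, treatment complication, progression, progression with
    complication, death) model of third-line treatment for chemorefractory
    metastatic colorectal cancer.  Provides DEALE conversion of survival
    medians to per-cycle transition probabilities, once-only complication
    accounting via expanded tunnel states, discounted cost and QALY accrual
    under configurable counting and discounting conventions, ICER and net
    monetary benefit outcomes, one-way deterministic (tornado) and
    probabilistic sensitivity analyses with cost-effectiveness acceptability
    curves, a microsimulation validation oracle, and a bundled scenario
    comparing TAS-102 plus bevacizumab combination therapy against TAS-102
    monotherapy from the Japanese health-care payer's perspective.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
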