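Package: poisoncea
Title: Cost-Effectiveness Modelling of Home Safety Interventions Against
    Childhood Poisoning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Probabilistic decision-analytic model comparing seven home
    safety intervention strategies (education, provision of low cost or free
    safety equipment, home safety inspection, fitting, and their
    combinations) for preventing unintentional poisoning in preschool
    children. Couples a stage-1 intervention decision tree with a six-state
    preschool Markov cohort model (ages 0-4) and a three-state long-term
    Markov model (ages 5-99), propagates parameter uncertainty by Monte
    Carlo probabilistic sensitivity analysis, and computes incremental
    cost-effectiveness ratios with strict and extended dominance,
    cost-effectiveness planes and cost-effectiveness acceptability curves,
    for both cost-effectiveness (poison cases averted) and cost-utility
    (QALY) analyses, in medicinal and non-medicinal poisoning variants with
    a ladder of twelve sensitivity scenarios. Includes an individual-level
    microsimulation oracle for validating the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
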