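Package: pocuscma
Title: Decision-Tree Cost-Minimisation Analysis of Point-of-Care
    Ultrasonography in General Practice
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a decision-analytic cost-minimisation model
    comparing general practice with and without point-of-care
    ultrasonography (POCUS) for vaginal bleeding in early pregnancy.
    Provides a validated decision-tree engine with expected-cost
    roll-back and an independent path-enumeration oracle, perspective-
    aware costing (societal versus healthcare sector) with equivalent
    annual cost annuitisation of capital items, a GP remuneration
    composition, one-way deterministic sensitivity analysis with
    tornado ranking, a perspective-switch scenario, and a seeded
    probabilistic sensitivity analysis with method-of-moments beta and
    gamma parameter distributions. The Danish early-pregnancy case
    study is bundled as a built-in fixture, together with generators
    for synthetic questionnaire panels and random models, and models
    can be declared in a YAML configuration file and driven from a
    command-line interface.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
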