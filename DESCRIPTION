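Package: foodscba
Title: Social Cost-Benefit Analysis of Food Pricing Policies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the 30-year societal effects of consumer price
    interventions on food -- a meat tax (15% or 30%) and a fruit and
    vegetables subsidy (10%) -- against a no-policy reference scenario.
    Own-price elasticities project consumption; a dynamic multistate
    (Markov-type) health model converts intake category shifts into
    chronic-disease incidence via relative risks and yields averted
    prevalent cases and quality-adjusted life years with Monte-Carlo
    uncertainty; life-cycle-analysis footprints with production efficiency
    gains quantify five environmental indicators; all effects are
    monetized (QALY value, environmental unit costs, cost of illness,
    productivity, rule-of-half consumer surplus, policy revenue) and
    discounted into stakeholder-stratified welfare ledgers with one-way
    sensitivity analyses. Ships a seeded synthetic-data generator
    emulating the required demographic, dietary, epidemiological and
    economic inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
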