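Package: ltra
Title: Long-Term Risk Adjustment Payment Simulation for Social Health
    Insurance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates morbidity-based risk-adjustment (risk equalization)
    payment schemes in social health insurance and contrasts the standard
    one-year capitation allocation with a long-term (ten-year) allocation in
    which scheduled payments are frozen at assessment. Includes enrollee
    cost-trajectory modelling (age gradient plus health-cost inflation),
    health-investment interventions with up-front cost multipliers and
    long-run savings, age-dependent assessment horizons, settlement transfers
    for enrollees switching insurers, insurer ledgers and intervention net
    present values, selection-incentive diagnostics under cost-prediction
    error, and a seeded synthetic-population generator for Monte-Carlo policy
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
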