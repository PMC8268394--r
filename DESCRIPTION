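Package: pamcea
Title: Cost-Effectiveness of Implantable Pulmonary-Artery-Pressure
    Monitoring in Chronic Heart Failure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-state Markov cohort model evaluating implantable
    pulmonary-artery-pressure monitoring (CardioMEMS) against usual medical
    care in NYHA class III heart failure, from Argentine third-party-payer
    perspectives (Social Security and Private Sector). Provides life-table
    mortality calibration via an excess-hazard correction factor,
    inverse-variance pooling of study hazard ratios, monthly-cycle cohort
    simulation with discounted costs and quality-adjusted life years,
    one-way (tornado) and probabilistic sensitivity analyses,
    cost-effectiveness acceptability curves, and scenario analyses of
    treatment-effect duration. A parametric Gompertz life-table generator
    and an individual-level microsimulation oracle support validation
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    ggplot2,
    optparse
Config/testthat/edition: 3
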