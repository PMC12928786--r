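Package: saltimpact
Title: Health Impact Modelling of Category-Specific Salt Reformulation Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage policy model for category-specific salt reduction
    targets. Stage one is a static microsimulation of a food-diary survey:
    per-person salt intake is recomputed under full compliance with per-100g
    (grocery) and per-serving (out-of-home) targets, corrected for dietary
    under-reporting against urinary-sodium reference means, and summarised
    with survey-weighted bootstrap confidence intervals. Stage two converts
    the salt change to a systolic blood pressure shift, computes population
    impact fractions on ischemic heart disease and stroke incidence, and
    propagates them through a proportional multistate lifetable to estimate
    cases averted, deaths, life expectancy, quality-adjusted life years and
    healthcare costs, with Monte Carlo uncertainty intervals and standard
    health-economic sensitivity analyses. A seeded synthetic-data generator
    produces every input table with the statistical structure the analysis
    assumes, so the full pipeline runs without access to restricted survey
    microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
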