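Package: steppath
Title: Daily Step Counts, Polygenic Risk, and Incident Obesity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how objectively measured physical activity
    modifies polygenic risk of obesity. Implements wearable step-count
    curation (day-level validity filters, monthly exposure aggregation,
    incident-obesity landmark definition), polygenic score residualization
    and incremental Nagelkerke R-squared, time-varying Cox proportional
    hazards models with restricted cubic splines and a drop-to-linear rule,
    multiple imputation by bootstrap predictive mean matching with Rubin
    pooling, inversion of fitted hazard-ratio curves to per-genetic-risk
    daily step targets with confidence-band propagation, and Breslow
    baseline-hazard cumulative incidence estimation. A synthetic-cohort
    generator with a known proportional-hazards event process and an
    encounter-driven BMI observation process makes every stage testable
    without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    survival,
    stats,
    utils,
    jsonlite,
    rlang,
    MASS
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
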