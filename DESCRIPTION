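Package: injurycost
Title: Employer-Perspective Costing of Occupational Injuries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the economic burden of occupational injuries from the
    employer's perspective using workers' compensation claim records. Direct
    costs are computed top-down from median medical and compensation payments
    scaled to the claim count; indirect productivity losses (absenteeism and
    presenteeism) follow the friction cost method with configurable
    multipliers; summaries report cost shares and currency conversion.
    Predictors of per-claim total cost are identified with a gamma
    generalized linear model with log link fitted by iteratively reweighted
    least squares, alongside collinearity (variance inflation factor,
    correlation screen) and normality diagnostics. A seeded synthetic cohort
    generator reproduces the marginal structure of a published Ethiopian
    manufacturing-industry claims cohort so that every pipeline stage is
    testable without access to raw compensation records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    yaml
Config/testthat/edition: 3
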