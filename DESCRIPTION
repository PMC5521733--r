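Package: tevtrade
Title: Trade-Offs Between Tropical Forest Ecosystem-Service Values and
    Agricultural Rents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for spatially explicit trade-off analysis
    between the economic benefits of converting tropical forest to
    agriculture and the externalities of that conversion. Implements a
    meta-analytic benefit-transfer model for ecosystem-service values
    (country random-intercept mixed models with exhaustive AICc model
    enumeration, delta-AICc selection, and Akaike-weight averaging),
    carbon-emission accounting and valuation under market and social
    price regimes, von Thunen-style agricultural rent estimation under
    four crop-replacement scenarios, net-impact integration, and joint
    Monte Carlo propagation of map, price, and model uncertainty.
    Includes a seeded synthetic-data generator so every stage is
    testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    car,
    lmtest,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
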