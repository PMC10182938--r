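Package: wqrisk
Title: Water Quality Indices and Probabilistic Nitrate Health Risk for Surface Reservoirs
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes the NSFWQI (weighted arithmetic) and IRWQISC (weighted
    geometric) water quality indices from piecewise-linear parameter rating
    curves, with quality classification and station/season aggregation.
    Provides deterministic chronic-daily-intake and hazard-quotient risk
    estimates for nitrate in drinking water across age groups, Monte Carlo
    uncertainty propagation of the hazard quotient, and variance-based Sobol
    sensitivity analysis (first-, second- and total-order indices) using a
    Saltelli sampling design with Jansen estimators and bootstrap confidence
    intervals. Includes a synthetic measurement-table generator emulating a
    multi-station seasonal reservoir monitoring campaign and packaged
    reference fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
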