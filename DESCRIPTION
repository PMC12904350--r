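Package: adaptcat
Title: Computerized Adaptive Testing Simulation for Dichotomous 3PL Item Banks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A simulation workbench for computerized adaptive testing (CAT)
    with dichotomously scored items under the three-parameter logistic (3PL)
    item response model. Provides expected-a-posteriori (EAP) scoring on a
    quadrature grid with posterior-SD standard errors, item selection by
    maximum posterior weighted information, dual stopping rules (standard
    error threshold and maximum test length), post-hoc simulation over a
    complete response matrix, a seeded synthetic-data generator for item
    banks and cohorts, and an evaluation battery (test-length summaries,
    theta-recovery RMSE, correlation-by-length curves, secondary stopping
    rule diagnostics, and standard-error reduction analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
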