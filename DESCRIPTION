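Package: mnrm
Title: Multidimensional Nominal Response Model for Response Styles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Joint measurement of substantive traits and response styles
    (extreme and midpoint responding) from Likert-type items with the
    multidimensional nominal response model using fixed, user-chosen
    scoring functions.  Provides EM marginal maximum likelihood
    estimation over rectangular quadrature, response-pattern expected a
    posteriori (EAP) scoring, and sum-score-to-EAP translation tables
    computed by a polytomous Lord-Wingersky recursion with
    nuisance-dimension marginalization, plus a simulator for generating
    response matrices from a specified model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
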