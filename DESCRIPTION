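Package: petitsuisse
Title: Factorial Formulation Analysis and Shelf-Life Kinetics for
    Fermented Dairy Gels
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing two-level factorial formulation studies of
    fermented dairy products such as Petit Suisse cheese. Implements
    physical-to-coded factor mapping for 2^k designs with center points,
    first-order response-surface fits with interaction (coded and
    physical-unit coefficients, regression ANOVA, R-squared), Derringer-Suich
    desirability functions with composite geometric-mean optimization over
    the factor space, and first-order microbial viability kinetics (specific
    death and growth rates, percent survival), syneresis indices and storage
    trend summaries for shelf-life series. Ships the reference seven-run
    buffalo Petit Suisse formulation dataset (inulin and xanthan gum factors)
    together with its 28-day lactic acid bacteria viability series, plus
    seeded generators of synthetic designs, viability and storage series for
    validation by parameter recovery.
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
    withr
Config/testthat/edition: 3
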