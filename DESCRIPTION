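Package: niptppr
Title: Personalised Posterior Risk Calculation for Non-Invasive Prenatal
    Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the personalised a posteriori risk (PPR) of foetal
    trisomy 13, 18 or 21 from a non-invasive prenatal test (NIPT) result.
    The observed Z-score is converted into a likelihood ratio between the
    trisomic and euploid models, with the foetal DNA fraction treated as a
    nuisance parameter and marginalised over a fixed value, a uniform
    range, or a weighted mixture of uniform ranges, and combined with the
    woman's a priori risk through a Bayes odds update. Includes sensitivity
    analytics for assay design, odds-notation parsing and bilinear
    interpolation of maternal-age by gestational-age risk tables, batch
    scoring of sample tables, PPR grid generation, a cohort simulator for
    self-validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
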