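Package: itemharmony
Title: Pre-Statistical Harmonization of Multi-Study Item Banks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the pre-statistical harmonization of item-level
    behavioral and psychometric data pooled across studies. Provides a
    crosswalk data model linking harmonized item constructs to
    study-specific source variables, a deterministic recoding engine
    (sentinel missing-code masking, direction reversal, shift-to-zero,
    dichotomization, sparse-category collapsing), an automated quality
    control battery for cross-study item comparability (sentinel codes,
    no-variability items, scale discrepancies, reverse-polarity
    candidates, conditional skip-pattern items), per-study two-parameter
    logistic item response theory fits by marginal maximum likelihood
    with limited-information fit statistics (M2, RMSEA, CFI, SRMR) and
    residual diagnostics for local dependence, and a synthetic
    multi-study item-bank generator with planted defects for validating
    every check against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
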