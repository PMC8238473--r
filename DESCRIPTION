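Package: cardiowell
Title: Cardiac Well-Being Indexes from Risk-Factor Data
Version: 0.1.0
Authors@R: person("cardiowell", "maintainers", email = "maintainers@cardiowell.invalid", role = c("aut", "cre"))
Description: End-to-end toolkit for computing and archiving cardiac well-being
    indexes. Generates calibrated synthetic risk-factor cohorts, cleanses
    records, selects the best disease classifier among five candidate families
    by a sensitivity/accuracy composite score under stratified
    cross-validation, maps predicted disease probability to an intuitive index
    in [-5, 5] through an anchored decreasing exponential, archives per-user
    measurements in a star-schema warehouse with a type-4 slowly changing user
    dimension and watermark-based incremental loading, and reports
    regression-weighted individual trends plus global population indexes
    sliced by gender, region and calendar.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
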