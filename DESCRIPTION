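Package: pnidesign
Title: Sample Size and Operating Characteristics for Dose-Optimization
    Trials with a Margin of Practical Non-Inferiority
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Designs randomized dose-optimization (dose-reduction) trials
    using a margin of practical non-inferiority: a pre-specified bound on
    the observed difference in efficacy (median survival time or response
    proportion) within which a reduced dose of an approved drug is deemed
    not materially different from the approved regimen. Provides
    closed-form sample-size and operating-characteristic calculations for
    time-to-event endpoints under the exponential survival model,
    exact-binomial and Monte Carlo calculations for binary endpoints,
    Kaplan-Meier estimation on individual patient data, bootstrap
    verification of calculated sample sizes by resampling patient-level
    data, margin calibration against conventional non-inferiority, and
    seeded synthetic-data generators, with JSON/CSV reporting and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
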