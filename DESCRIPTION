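Package: loudsum
Title: Binaural Broadband Loudness Summation and Loudness-Based Hearing
    Aid Gain Prescription
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models categorical loudness functions (categorical units
    versus level), simulates adaptive categorical loudness scaling on
    virtual hearing-impaired listeners under narrowband
    loudness-normalization gains, computes trueLOUDNESS-style broadband
    binaural gain prescriptions and compression ratios, and quantifies
    excess binaural broadband loudness summation (the level difference at
    40 categorical units, dL40) together with its prevalence and
    audiological predictors. Includes a calibrated synthetic cohort
    generator so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
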