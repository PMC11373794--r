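Package: anthrobias
Title: Prevalence Bias in Anthropometric Z-Score Indicators Under
    Non-Directional Measurement Error
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how non-directional (zero-mean) measurement
    error biases threshold-based child anthropometric prevalence indicators
    such as stunting, wasting and underweight. Provides closed-form and
    Monte Carlo engines for the prevalence of z-scores below a cutoff,
    an error-injection simulator that tracks false-positive and
    false-negative threshold crossings, gridded prevalence-bias maps
    anchored at a reference standard deviation, survey-level data-quality
    assessment (weighted z-score moments, estimated bias ranges, age
    heaping ratio, digit-preference tests, cross-survey correlation), and
    a synthetic survey generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
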