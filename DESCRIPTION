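Package: optrial
Title: Optimal Design of Biomarker-Stratified Confirmatory Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for planning a biomarker-stratified multi-arm confirmatory
    (phase III) trial from an earlier exploratory (phase II) study. Candidate
    treatment-by-subgroup hypotheses are weighted by conjugate
    normal-inverse-gamma Bayesian analysis of the phase II data combined with
    bootstrap resampling; the analysis model for the future trial is
    reformulated parsimoniously so that every selected contrast is estimable;
    a weighted L-optimal continuous design is computed over the
    biomarker-treatment support and converted to per-subgroup randomization
    probabilities; and competing randomization schemes are compared by Monte
    Carlo simulation of power, type I error and the expected number of
    correct rejections.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
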