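Package: expopool
Title: Monte Carlo Pooling of Biomarker Concentration Summaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts heterogeneous per-study summary statistics of
    biomarker concentrations (arithmetic or geometric means, medians with
    interquartile ranges or min-max ranges, means with confidence
    intervals) into simulated individual-level values by seeded
    inverse-CDF Monte Carlo with a limit-of-detection floor, pools the
    simulated values into stratified geometric-mean exposure estimates
    across sampling period, province, sex and age band, and tests
    group differences (Mann-Whitney U) and associations of province-level
    estimates with environmental covariates (Pearson correlation).
    Includes a synthetic literature-corpus generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
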