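Package: toxmatrix
Title: Time-Response Lethal-Time Modelling and Weighted Response-Matrix
    Scoring for Direct Toxicity Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for direct toxicity assessment (DTA) of environmental
    water samples on marine invertebrates from time-course survival data.
    Fits log-logistic and Weibull time-response curves to percent survival,
    selects among candidate model families by AIC, and inverts the selected
    curve to lethal-time estimates (LT10, LT50) with delta-method 95
    percent confidence limits. Implements a weighted five-criterion
    weight-of-evidence response matrix that classifies each species x
    test-solution x round combination as Response or No response and
    summarizes relative toxicity of solutions and relative sensitivity of
    species. Includes a synthetic trial generator with latent individual
    death times for parameter-recovery experiments, Microtox EC50
    interpretation bands, and brine salinity mass-balance utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
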