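Package: sejcm
Title: Classical-Model Scoring and Pooling for Structured Expert Judgment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores probabilistic assessments elicited as 5/50/95 percent
    quantiles with the Classical Model's statistical-accuracy (calibration
    p-value) and Shannon-relative-information measures, builds equal-weight
    and performance-weighted pooled decision makers with in-sample
    optimisation of the accuracy cut-off, and provides cross-panel
    evaluation analytics (performance-weight versus equal-weight
    comparison, informativeness-accuracy rank-correlation structure)
    together with a synthetic elicitation-study generator emulating a
    large multi-panel attribution exercise.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
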