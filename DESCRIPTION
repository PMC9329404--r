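Package: strataMR
Title: Collider-Safe Stratified Mendelian Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stratified Mendelian randomization that avoids collider bias by
    stratifying on the residual collider, the residual from regressing a
    candidate stratifying variable on the genetic instrument. Provides the
    ratio (Wald) instrumental-variable estimator, residual-collider
    construction, quantile-stratum causal estimates, Cochran's Q homogeneity
    test and a fixed-effect meta-regression trend test, together with a
    Monte-Carlo simulation framework (scenarios with exposure-driven,
    outcome-driven and binary-outcome colliders) for quantifying collider
    bias, type-I error and heterogeneity-test power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
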