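Package: dietiq
Title: Pregnancy Diet-Quality Scoring and Diet-Brain-IQ Association and
    Mediation Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a 15-component diet-quality score for pregnancy
    (adherence to Dutch dietary guidelines, range 0-15), a synthetic
    mother-child cohort generator emulating the statistical structure of
    prenatal nutrition studies of child brain morphology and cognition,
    covariate-adjusted linear association models with Benjamini-Hochberg
    false-discovery-rate control, multiple imputation of covariates by
    chained equations with Rubin's-rules pooling, and quasi-Bayesian
    Monte Carlo causal mediation analysis decomposing diet effects on IQ
    through brain volumetric mediators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
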