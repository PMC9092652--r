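Package: nestlme
Title: Nested Linear Mixed Effects Models for Longitudinal Group Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimation and inference for two-group longitudinal growth
    trajectories with nested random effects (e.g. mice nested in donors) and
    optional AR(1) residual correlation. Provides an exact REML/ML likelihood
    engine based on direct evaluation of the marginal covariance, a ladder of
    eight named model parameterizations ranging from a maximal
    donor-plus-mouse random intercept and slope model down to an ordinary
    linear model, Wald and likelihood-ratio tests plus parametric bootstrap
    tests for boundary variance components, BLUP-based fitted trajectories and
    residual diagnostics, a multivariate-normal synthetic-data generator
    emulating a nested fecal-transplant mouse growth study, and a Monte-Carlo
    harness estimating type I error and power of the group-by-time interaction
    test under correctly specified and misspecified covariance structures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    nlme,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
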