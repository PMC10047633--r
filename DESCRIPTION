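Package: hurdlemm
Title: Bayesian Hurdle Log-Normal Mixed Models for Repeated Behavioural Measures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Bayesian multivariate hurdle log-normal mixed models to
    repeated behavioural trials recorded in several ecological contexts, with
    treatment-specific among-individual variances, treatment-specific residual
    (within-individual) variances, treatment-specific zero-probability
    (hurdle) intercepts on the logit scale, and egg-mass (clutch) random
    effects.  A companion Gaussian random-slope model handles repeated
    body-size measurements.  Derived statistics cover adjusted repeatability
    (among-individual variance over total variance), treatment contrasts with
    highest-posterior-density intervals, hurdle probabilities on the data
    scale, and among-individual cross-context correlation matrices
    (behavioural syndromes).  A synthetic-data generator reproduces the
    repeated-measures design these models assume, so the whole analysis is
    testable end to end against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
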