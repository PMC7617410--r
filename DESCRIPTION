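Package: ddmconf
Title: Drift-Diffusion Models of Decision Confidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative simulation, trial-by-trial analytic likelihoods, and
    model comparison for drift-diffusion-model (DDM) accounts of decision
    confidence in a two-array dot-comparison task. Implements a family of DDM
    variants combining drift-rate variability, linearly collapsing decision
    thresholds, and accumulator or (mis)calibrated Bayesian time-penalty
    confidence readouts; scores binned confidence reports conditional on the
    stimulus, response and response time via a Gaussian final-state
    approximation; and provides maximum-likelihood fitting with multi-start
    optimization, five-fold cross-validation, fixed- and random-effects model
    comparison, plus the model-free behavioral battery (pipeline-duration
    estimation, ordinal probit evidence regressions, psychophysical kernels).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
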