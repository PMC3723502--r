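Package: deltamix
Title: Change-Point Inference with Run-Length Filtering and Mixtures of
    Delta Rules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Online Bayesian inference for univariate change-point
    processes in conjugate exponential families (Bernoulli rate, Gaussian
    mean with known variance, Gaussian scale with known mean).  Implements
    the exact truncated run-length filter and a lightweight approximation
    that mixes a small set of fixed-learning-rate Delta rules whose
    weights track an approximate run-length distribution.  Includes
    generators for change-point data and a predictive-inference task,
    Monte-Carlo estimation of prediction error with optimisation of node
    learning rates, maximum-likelihood fitting of models to subject
    prediction sequences with BIC scoring, random-effects group model
    selection, and model-recovery confusion matrices.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
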