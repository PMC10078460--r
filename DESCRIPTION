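Package: mixedde
Title: Differential Expression Inference with Negative Binomial Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pairwise differential-expression analysis of RNA-seq count
    matrices using per-gene negative binomial generalized linear mixed
    models with a fixed two-level condition effect and an optional random
    intercept, fitted by Laplace approximation and tested with Wald
    statistics under Benjamini-Hochberg or Bonferroni correction. Includes
    the accompanying count-matrix preprocessing pipeline (scale correction,
    relative-log-expression normalization, expression and low-CPM filters),
    per-gene overdispersion diagnostics and a common-dispersion biological
    coefficient of variation estimate, a count simulator with known
    differentially expressed genes and truncated-normal random-effect
    injection, and a precision/recall/accuracy benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    edgeR,
    glmmTMB,
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
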