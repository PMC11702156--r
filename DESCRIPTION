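Package: eaic
Title: Extended AIC for FWER-Controlled Variable Selection in High-Dimensional Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Information criteria for sparse model selection in high-dimensional
    linear and logistic regression, centred on the extended AIC (EAIC), whose
    per-variable penalty 2*x[p,alpha] is the multiplicity-corrected
    likelihood-ratio threshold for p candidate regressors and therefore gives
    asymptotic family-wise error rate (FWER) control at a user-chosen level
    when regressors are independent. Includes the classical AIC and BIC and
    the dimension-adjusted RIC, mAIC, mBIC and EBIC; the closed-form
    distribution theory of the maximal likelihood-ratio statistic (critical
    bounds, asymptotic FWER, coincidence levels between criteria); the full
    selection procedure (LASSO regularization path, unpenalized refit of every
    candidate support, criterion minimization); and simulation-study drivers
    that estimate FWER, FDR and sensitivity on synthetic Toeplitz-correlated
    Gaussian designs with signal-to-noise-ratio-calibrated coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    stats,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
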