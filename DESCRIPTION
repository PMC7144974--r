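Package: tsgrowth
Title: Gompertz and Logistic Growth Curves on Continuous and Discrete Time
    Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates a catalog of continuous and discrete Gompertz-type
    (first type, Zwietering, Gompertz-Laird, second type) and logistic
    (3- and 4-parameter) growth curves derived through time-scales
    calculus, together with the linear dynamic equations they solve.
    Provides the calculus primitives (circle plus/minus/dot, generalized
    exponential functions, delta derivative) on the real and integer time
    scales, independent dynamic-equation solvers used to verify every
    closed form, seeded nonlinear least-squares fitting with multi-start
    initialization, six forecast-error metrics (RMSE, RRMSE, MAE, MAPE,
    Theil's U1/U2), a p-value and adjusted R-squared based model-ranking
    rule, and a synthetic trajectory generator for parameter-recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
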