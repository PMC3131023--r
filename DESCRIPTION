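Package: succmib
Title: Delayed-Logistic Succession Modelling with Carabid Mean Individual Biomass
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying forest succession on degraded areas using
    the Mean Individual Biomass (MIB) of carabid beetles as a numerical state
    variable. Computes MIB from pitfall-trap catch tables, tests the MIB-age
    association with Spearman rank correlation (exact permutation p-values for
    small samples), models succession with a four-parameter delayed logistic
    curve (initial degradation level, delay, increase rate, recovery level),
    estimates the parameters from chronosequence series by profiled nonlinear
    least squares, and simulates carabid communities whose expected MIB follows
    a prescribed trajectory so every stage can be verified without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
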