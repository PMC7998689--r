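Package: surftens
Title: Surface Tension of Liquid Organic Acids by Neural-Network and
    Corresponding-States Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the surface tension of liquid organic acids from a small
    set of fluid constants (critical temperature, normal boiling temperature,
    acentric factor). Implements a feed-forward multilayer perceptron with one
    sigmoid hidden layer trained by a damped Gauss-Newton (Levenberg-Marquardt)
    optimiser with early stopping on a held-out test set, together with the
    deviation statistics (signed percent deviation, absolute average deviation,
    maximum deviation, RMSE, R squared), four classical corresponding-states
    baseline correlations, effect-factor feature ranking, a hidden-layer-size
    sweep with multi-restart selection, and a synthetic-data generator that
    emulates multi-source experimental surface-tension corpora for end-to-end
    testing. Tibble-first interfaces chain with the pipe; fitted models support
    tidy(), glance(), predict() and autoplot().
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    broom,
    minpack.lm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
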