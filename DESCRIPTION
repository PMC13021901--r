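Package: solubag
Title: Bat-Algorithm-Tuned Bagging Ensembles for Supercritical CO2
    Solubility and Density Correlation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Correlates drug solubility in supercritical carbon dioxide and
    the solvent density with temperature and pressure using bagged ensembles
    of three base regressors (ridge-stabilized polynomial regression,
    K-nearest neighbours, and a log-link gamma generalized linear model),
    with hyperparameters selected by a bat-algorithm metaheuristic that
    minimizes cross-validated prediction error.  Ships the 32-point
    phenytoin/CO2 reference dataset, a synthetic surface generator for
    method validation, evaluation metrics (R2, RMSE, AARD%, maximum error),
    permutation feature importance, and effect-curve/response-surface
    utilities, all with tibble-first interfaces.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
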