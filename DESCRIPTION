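Package: hospanel
Title: County-Level Hospital Demand Modelling on Balanced Weekly Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits linear mixed models for log per-100k hospitalization and
    ICU usage rates on balanced county-week panels, with a within-county
    ARMA-structured residual covariance (error variance, common correlation
    factor, and dampening parameter) estimated by restricted maximum
    likelihood. Includes lagged-case and moving-average feature engineering,
    a synthetic panel generator with known ground truth for parameter
    recovery studies, exogenous epidemic scenario trajectories
    (peak-and-valley, unexpected spike, slow burn, rapid vaccination),
    multi-week demand forecasting, and hospital/ICU capacity-stress
    summaries at county, state, regional and national resolution.
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
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
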