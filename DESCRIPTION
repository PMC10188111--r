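Package: skelage
Title: Skeletal Age: Fracture-Associated Mortality as Years of Life Lost
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating 'skeletal age', an effective-age metric that
    translates the excess mortality after a fragility fracture into years of
    life lost. The package simulates registry-style cohorts of adults aged
    50+, builds immortal-time-bias-safe counting-process datasets with
    pre/post-fracture exposure splitting and Charlson comorbidity scoring,
    fits time-dependent Cox proportional-hazards models with cluster-robust
    variance, and transforms site-specific hazard ratios through the Gompertz
    law of mortality (closed-form remaining life expectancy via the
    exponential integral) into years of life lost and skeletal age with
    confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    survival,
    stats,
    tools,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
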