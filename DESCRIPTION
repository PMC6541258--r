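Package: lurefx
Title: Attractant Effects on Detection at Baited Camera-Trap Stations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how attractant (bait and scent lure)
    freshness and survey effort change species-specific detection at
    camera-trap stations. Processes capture logs into independent events
    and daily detection histories, fits single-season occupancy models
    with observation-level detection covariates (days since attractant
    refresh, cumulative and total effort) selected by AICc, estimates
    diel activity with von Mises circular kernel densities, and tests
    short-term (1-7 day) station-visitation response to attractant
    refresh against a randomization null built from each species'
    activity pattern. Includes a synthetic-survey generator with known
    ground truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    tibble,
    readr,
    lubridate,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    digest,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
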