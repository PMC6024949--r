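Package: aqburden
Title: Health Impacts and Economic Losses Attributable to Ambient PM2.5
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: City-level assessment of the health burden and monetized economic
    losses attributable to ambient fine particulate matter (PM2.5). Implements
    the log-linear (Poisson relative-risk) exposure-response model for
    attributable cases per health endpoint, dual-bound mortality valuation
    (value-of-statistical-life benefit transfer for the upper bound, discounted
    amended-human-capital for the lower bound), cost-of-illness morbidity
    valuation, city and national aggregation with year-over-year change
    analysis, and Monte Carlo propagation of input uncertainty. Includes a
    calibrated synthetic panel generator emulating a 190-city, 2014-2016
    Chinese city panel so the full pipeline is reproducible without restricted
    monitoring-station or statistical-bulletin data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
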