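Package: awaredose
Title: Antibiotic Consumption and Cost Metrics with ATC/DDD and AWaRe
    Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts pack-level antibiotic sales and procurement records
    into WHO defined daily doses (DDDs), normalizes consumption to DDDs per
    1000 population per day (DID), and computes spending metrics (total
    cost, cost per DDD, per-capita cost) under selectable price bases (MRP,
    wholesale, procurement).  Produces stratified share tables by route,
    sector, AWaRe group and ATC level, supports a price-basis sensitivity
    analysis for public-private cost shares, and ships a seeded synthetic
    data generator with exact ground-truth aggregates so the whole pipeline
    is testable end to end without proprietary sales data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    readr,
    tibble,
    rlang,
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
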