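Package: fopscan
Title: Front-of-Pack 'High in' Nutrition-Symbol Surveillance for Packaged Foods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for food-supply surveillance built around the Canadian
    front-of-pack (FoP) "high in" nutrition-symbol regulation. Classifies
    packaged-food products against configurable threshold rules (daily values,
    category reference amounts, tiered thresholds and exemptions), merges
    label databases with sales data by product code, computes sales-weighted
    nutritional portraits per food category, and simulates uniform
    reformulation (e.g. 5/10/15 percent reductions of sodium, saturated fat or
    total sugar) to quantify percentage-point shifts in symbol prevalence.
    Includes a seeded synthetic supply generator so every stage of the
    pipeline runs without proprietary sales data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
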