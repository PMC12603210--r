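Package: pollishock
Title: Market and Welfare Consequences of a Wild-Pollinator Collapse
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives crop and commodity productivity shocks from pollination
    dependence ratios and wild-pollinator contribution shares, propagates them
    through a stylized multi-region partial-equilibrium agri-food market model
    with Armington trade, and reports welfare (consumer and producer surplus,
    tariff revenue), food-security (per-capita calorie and micronutrient
    availability) and sensitivity-grid results. Ships a seeded synthetic-data
    generator emulating the structure of FAOSTAT-style production and market
    databases so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    readr,
    generics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
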