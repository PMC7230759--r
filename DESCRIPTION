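Package: fopcompare
Title: Comparison of Front-of-Package Nutrient Profiling Schemes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies prepacked food products under ten front-of-package
    nutrient profiling schemes (Nutri-Score, Health Star Rating, UK FSA
    traffic light, Protective Food symbol, Keyhole, Choices, Finnish Heart,
    WHO-Europe, Ofcom NPM and FSANZ NPSC), harmonises the verdicts to a
    binary "healthier" flag, and compares schemes by per-category
    proportions, sales-weighted proportions, Cohen's kappa agreement and
    symbol-versus-rating conflict scenarios. Includes a seeded synthetic
    food-supply generator emulating category-typical nutrient distributions
    and heavy-tailed retail sales for the five studied categories
    (breakfast cereals, pasta, cheese, yoghurt products, cooking oils).
    All scheme point tables and threshold limits ship as versioned,
    auditable configuration files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
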