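Package: corewood
Title: Basic Wood-Density Estimation from Increment-Core Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates basic wood-density (oven-dry mass per green volume)
    from increment-core samples measured at ambient humidity, using a
    closed-form conversion built on a fiber-saturation shrinkage model in
    which volumetric shrinkage is proportional to basic specific gravity.
    Includes the full core-sample processing chain (elliptic-cylinder
    volume, ambient density, eliminated moisture, basic density), schema
    readers, validators and summary reports for forest-inventory tree and
    wood-density tables, species-level density aggregation with
    light/medium/heavy classification and an among/within-species variance
    partition, a seeded forward-model generator of synthetic core and site
    datasets for end-to-end verification, and attribute-level tabulation
    of forest-vegetation provinces (category reclassification, province
    naming, area shares).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    lme4,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
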