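Package: ozoneyield
Title: Ozone Crop-Risk Assessment from Phytotoxic Ozone Dose to Production Loss
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for gridded crop ozone-risk assessment:
    accumulates phytotoxic ozone dose (POD3IAM) over 90-day growing-season
    windows on a grid, converts dose to percentage yield loss through a linear
    flux-effect relationship fitted by variance-weighted least squares,
    converts yield loss to production loss using gridded production data with
    per-sub-region seasonal splits and survey-derived conversion factors,
    aggregates losses to administrative sub-regions, and scores co-located
    crop stresses (soil nutrients, drought, flood, temperature, deprivation,
    ozone) into a composite crop stress score. A seeded synthetic-data module
    emulates every input so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
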