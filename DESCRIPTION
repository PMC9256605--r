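Package: coastimpact
Title: Potential Climate Impacts on Fisheries and Agriculture in Coastal Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Community-scale assessment of potential climate-change impacts on
    the two food-producing sectors coastal communities depend on: fisheries and
    agriculture. Computes livelihood sensitivity indices from ranked household
    occupation surveys, extracts sector exposure (mid-century percent change in
    total consumer biomass and rain-fed crop yield) from multi-model gridded
    projection ensembles at survey sites, combines exposure and sensitivity
    into a relative potential-impact score, and runs the comparative statistics
    (country random-effect means, paired sector differences, double-burden
    rates, material-style-of-life wealth regressions with bootstrap standard
    errors). Includes a synthetic-data generator that emulates household
    surveys, gridded ensembles, and coastal population rasters so the full
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    ncdf4,
    geosphere,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
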