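Package: cytocampaign
Title: Hourly-Scale Analysis of Automated Pulse-Shape Flow Cytometry Campaigns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse moored-buoy campaigns of automated
    pulse-shape ("scanning") flow cytometry at a two-hourly cadence. Generates
    synthetic listmode samples (per-particle five-channel optical pulse shapes)
    for six phytoplankton clusters driven by nutrient, wind and precipitation
    forcing with synchronized cell division; computes per-particle descriptors
    (pulse area, maximum, length), applies acquisition trigger thresholds and
    polygon gating on cytogram axes, and converts gated counts to cell
    concentrations via analysed volume. Provides a from-scratch local
    polynomial (loess) smoother with tricubic weights for regularizing
    irregular series onto an hourly grid with pointwise standard errors and
    slopes, abundance-pulse onset detection from slope sign changes, windowed
    cross-correlation against environmental drivers with lag search, and diel
    cycle decomposition by differencing two loess spans with hour-of-day
    boxplot statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
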