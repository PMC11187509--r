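Package: opioidtrends
Title: Detecting Sustained Reductions in Organizational Opioid Prescribing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for surveillance of opioid prescribing in monthly
    organization-level dispensing panels. Computes three standard opioid
    prescribing measures (total oral morphine equivalence per 1000 registered
    patients, high-dose opioid items as a percentage of regular opioid items,
    and high-dose opioid items per 1000 patients), fits a broken-linear-trend
    (trend-indicator-saturation) model to each organization's series to locate
    and size sustained reductions, applies a screening cascade for closed,
    small and zero-denominator organizations, ranks organizations by
    proportional reduction, and summarizes peer variation as monthly decile
    charts. Includes a synthetic panel generator with known injected changes
    so the whole pipeline is testable end to end without access to national
    dispensing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
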