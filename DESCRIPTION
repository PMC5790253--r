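Package: mpaeval
Title: Effectiveness Evaluation of No-Take Marine Reserves from BACI Monitoring Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes biological and socioeconomic indicators from underwater
    visual-census transect surveys and fishery landings records, estimates the
    effect of a no-take marine reserve with a before-after-control-impact
    difference-in-differences regression using heteroskedasticity-robust
    standard errors, adjusts fishery income by a consumer price index, scores
    governance survey responses against an editable rubric, and renders a
    color-coded effectiveness scorecard plus a technical report. Includes a
    seeded simulator for BACI survey data, landings series and governance
    responses with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    sandwich,
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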