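Package: vaxequity
Title: Multivariate Vaccine Equity Measurement from Child-Level Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring equity in childhood immunization from
    child-level household-survey microdata (DHS-style). Derives zero-dose,
    fully-immunized-for-age and complete-schedule indicators from per-dose
    records and a national immunization schedule; ranks children either by
    household wealth alone or by a composite model-based propensity for
    relative disadvantage built from multiple unfair factors (wealth,
    maternal education, district, urban/rural residence, sex, health
    insurance); computes survey-weighted concentration indices (plain,
    Wagstaff-normalized and Erreygers-corrected) with regression-based or
    bootstrap uncertainty; decomposes composite inequity into per-factor
    contributions with a regression-based concentration-index decomposition;
    and reports absolute equity gaps between the most and least advantaged
    quintiles. Includes national, per-district and multi-survey trend
    harnesses, plus a synthetic microdata generator with exactly enumerable
    ground truth for validation.
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
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
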