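Package: rtmortality
Title: Quality Assessment and Garbage-Code Correction of Road Traffic Mortality Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to assess the coding quality of ICD-10 civil-registration
    cause-of-death data and to correct road traffic mortality statistics for
    nonspecific ("garbage") codes. Classifies deaths into five nonspecific
    categories (ill-defined cause, undetermined intent, unspecified
    unintentional injury, unspecified transport crash, unspecified road
    traffic), redistributes them to specific causes by the proportionate
    method with adaptive temporal windows, computes age-standardized overall
    and road-user-specific mortality rates before and after correction,
    estimates geometric-mean average annual change rates, and projects deaths
    to 2021 and 2030 with on-track classification against the 50% reduction
    target. Includes a synthetic vital-registration panel simulator with
    known ground truth for validating every stage of the cascade.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
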