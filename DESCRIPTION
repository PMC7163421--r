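Package: eship2
Title: Blood Pressure Device Validation Under the ESH International
    Protocol (2010 Revision)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Method-comparison analysis for validating automated blood
    pressure monitors against a reference device following the European
    Society of Hypertension International Protocol, 2010 revision
    (ESH-IP2).  Builds most-favorable paired comparisons from
    nine-reading measurement sessions, classifies paired differences
    into the protocol's nested tolerance bands, applies the part 1 /
    part 2 / part 3 pass criteria for systolic and diastolic pressure
    and heart rate, and computes Bland-Altman agreement statistics.
    Includes a seeded synthetic cohort simulator with configurable
    device error models (additive bias, proportional bias, observation
    noise, within-session drift) and Monte-Carlo estimation of the
    protocol's pass probability under a given device error model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
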