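Package: pollendiary
Title: Seasonal Symptom Profiles of Grass Pollen Allergy Sufferers from
    Crowd-Sourced Diary Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse crowd-sourced hay-fever diary data against daily
    airborne grass pollen concentrations. Delimits the grass pollen season from
    cumulative pollen counts (1%/95% rule), computes the Annual Pollen Integral
    (APIn), filters diary users to likely grass pollen allergy sufferers by
    positive significant symptom-pollen rank correlation and minimum adherence,
    imputes missing daily symptom scores by k-nearest-neighbour over day of
    season and pollen concentration, partitions the season three ways (APIn
    tertiles, phenological flowering dates, per-user symptom-load tertiles),
    assigns each user to the season section of peak symptom severity, and
    summarises cross-year profile stability. Includes a synthetic pollen-season
    and diary-cohort generator with known ground truth so the whole pipeline is
    testable without access to personal diary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
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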