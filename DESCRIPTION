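Package: myelolot
Title: Treatment Lines and Triple-Class Exposure from Multiple Myeloma Claims
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives newly diagnosed multiple myeloma (NDMM) cohorts from
    longitudinal administrative claims tables (diagnoses, oral and injectable
    prescriptions, procedures), builds treatment lines and regimen segments
    with a 56-day regimen formation window and gap-based line-transfer rules,
    classifies regimens against a named catalogue, determines per-line and
    cumulative triple-class exposure (TCE: immunomodulatory drug, proteasome
    inhibitor and anti-CD38 antibody), and produces the standard cohort
    summary tables with explicit denominator and rounding conventions.
    Includes a synthetic claims generator with ground-truth sidecars so the
    whole pipeline is testable without access to a proprietary database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
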