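Package: qcrpn
Title: Empirical Occurrence and Detectability Estimation for FMEA Risk
    Priority Numbers from Layered QC Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the occurrence (O) and detectability (D) components
    of failure modes and effects analysis (FMEA) risk priority numbers from
    counts of failure modes caught in two sequential quality-control checks,
    as recorded for example during initial and first-weekly physics chart
    checks in a radiation oncology clinic.  Provides TG-100-style 10-point
    scale mappings between probabilities and scores, consistency checks of
    observed catch counts against published consensus (O, S, D) values with
    Monte-Carlo tail probabilities and parametric-bootstrap intervals, and a
    seeded clinic-QC simulator (per-plan Bernoulli failure occurrence passed
    through sequential imperfect checks, with optional unequal per-layer
    efficacy and under-reporting) for parameter-recovery and bias studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
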