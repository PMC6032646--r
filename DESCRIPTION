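Package: tremorkit
Title: Quantitative Tremor Analysis from Upper-Limb Inertial Sensor Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify parkinsonian kinetic and postural tremor from
    multi-sensor upper-limb inertial measurement unit (IMU) recordings.
    Provides causal high-pass preprocessing with gravity removal, periodogram
    power spectral density and cross-axis dominant-frequency detection,
    approximate entropy (ApEn) and root-mean-square tremor intensity, trial
    aggregation into per-subject feature tables, and one-way ANOVA group
    comparisons (patients versus controls, and clinical-score strata). Includes
    a seeded synthetic-cohort generator that emulates tremor oscillation,
    voluntary movement, gravity and sensor noise so the full pipeline is
    testable without clinical data, and an end-to-end pipeline runner with a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
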