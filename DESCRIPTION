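Package: brinleysim
Title: Simulated Multi-Study Stroop Data for Evaluating Brinley Plots and
    Multilevel Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates multi-study Stroop reaction-time data with known
    underlying structure (two age groups by two trial types, AR(1)
    intertrial correlation, between-study disturbances) and analyzes each
    simulated case two ways: a study-level Brinley mixed regression of
    older-adult condition means on younger-adult condition means with a
    full-versus-restricted likelihood-ratio comparison, and a three-level
    multilevel model of trial-level response times (trials within
    participants within studies). Renders standard and modified Brinley
    plots, the latter adding study-specific segments linking congruent and
    incongruent condition means and a no-age-difference reference line.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    grDevices,
    lme4,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
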