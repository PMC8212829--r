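Package: clineshift
Title: Predict Population-Level Allele Frequency Shifts Under Changed Climates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts population-level shifts in allele frequencies between a
    baseline and a changed (future or paleo) climate with a two-step pipeline:
    a redundancy-analysis (RDA) count model calibrated on baseline allele
    counts and climate, followed by a binomial penalized-spline correction
    that maps the raw RDA predictions onto valid frequencies in [0, 1] with
    confidence limits. Also provides AMOVA computed from the RDA
    decomposition, variance-inflation-factor variable subsetting,
    environmental-novelty scoring for changed climates, a synthetic
    cline-scenario generator with known ground truth, and a suite of
    shift visualizations (dot, pie, moon, waffle, geographic smoothed
    surfaces, population-shift ordinations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
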