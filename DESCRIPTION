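Package: swamyloid
Title: Sleep Slow-Wave Activity Features and Longitudinal Amyloid-PET Accumulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline linking NREM slow-wave activity extracted from
    polysomnographic EEG to annualized amyloid-PET accumulation. Reads EDF
    recordings and 30-s hypnograms, computes relative power spectral density in
    seven bands (slow oscillation through low gamma) per epoch, detects
    slow-wave negative half-waves and their downslopes in the slow-oscillation
    and delta ranges, annualizes two-timepoint PiB-PET SUVR on the log scale
    with centiloid conversion, and fits per-SD standardized linear models with
    backward elimination, collinearity checks, paired effect sizes and
    quartile predictions. Includes seeded synthetic EEG and cohort generators
    with analytic ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    readr,
    rlang,
    ggplot2,
    signal,
    MASS,
    withr,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    broom,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
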