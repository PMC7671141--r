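Package: odbatools
Title: Time and Activity Budgets from Tri-Axial Accelerometry
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Computes overall dynamic body acceleration (ODBA) from tri-axial
    accelerometer traces with rate-dependent running-mean gravity compensation,
    detects nightly activity onset and offset by Gaussian-kernel smoothing with
    a median threshold, references event times to civil twilight computed from
    solar geometry, aligns weather-station records to daily and twilight-centred
    windows, and fits linear mixed-effects models of activity responses with
    least-squares means and Tukey-adjusted stage contrasts. Includes a
    ground-truthed simulator of accelerometer deployments, weather, and
    twilight tables, and a reproducible end-to-end pipeline with a run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    lme4,
    lmerTest,
    emmeans,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
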