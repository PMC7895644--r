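Package: smoketop
Title: Smoking Topography from Wrist Accelerometry and Puff-Level Device Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify smoking topography - puff durations and
    interpuff intervals - from wrist-worn accelerometer traces and from
    mouthpiece topography device logs, and to compare the two methods.
    Includes a laboratory-session simulator with known ground truth
    (gesture-signature accelerometer traces plus paired device logs with
    configurable artifacts), a hysteresis-based puff-gesture segmenter,
    plausibility cleaning and outlier substitution for device logs, and
    per-participant and pooled agreement statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
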