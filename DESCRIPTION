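Package: photoavoid
Title: Fiber-Photometry and Behavioral Analysis for Cued Avoidance Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for fiber-photometry recordings collected during
    active-avoidance, reward-approach and open-field paradigms. Computes
    isosbestic-corrected dF/F with photobleaching normalization, fits an
    event-kernel linear encoding model with shuffled-event delta-R2 model
    comparison, measures lagged cross-covariance between neural signal and
    locomotor speed, detects movement epochs and video-based freezing, scores
    trials, and provides the group-level photometry and optogenetic analyses.
    Includes a synthetic-session generator with known ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    emmeans,
    optparse,
    testthat (>= 3.0.0),
    tidyr,
    tiff
Config/testthat/edition: 3
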