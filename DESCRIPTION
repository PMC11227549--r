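Package: foragedm
Title: Approach-Avoid Decision-Making Analysis for Freely Foraging Rodents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis stack for cost-benefit foraging tasks in which a rodent
    decides, trial by trial, whether to approach a cued feeder offering a
    sucrose reward paired with an aversive light cost. Provides readers,
    writers and consistency checks for tracking streams and trial logs; an
    arena simulator with a known two-factor logistic choice policy for
    ground-truth testing; per-trial spatiotemporal behavioral features
    (distance traveled, travel pixels, high-speed runs, stopping points,
    rotation points, approach and reaction time, zone occupancy); psychometric
    and neuroeconomic model fitting (1D/2D logistic choice surfaces, decision
    boundary, marginal-utility curvature, sigmoid/parabola shape
    classification); and fuzzy c-means strategy clustering with modified
    partition coefficient model selection, per-rat strategy profiles and
    condition-shift statistics (Kolmogorov-Smirnov, chi-squared).
License: MIT
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
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
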