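Package: painfreq
Title: Measurement-Frequency Evaluation for Weekly Pain Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to study how often a longitudinal pain outcome needs to be
    measured. Implements the analysis pipeline of a weekly SMS-based low back
    pain follow-up: per-subject piecewise-linear (free-knot spline) trajectory
    fits, Ward plus K-means clustering of the spline parameters with
    Calinski-Harabasz selection of the number of clusters, comparison of six
    measurement-frequency designs via Cohen's kappa and quadratic-weighted
    kappa, cluster trajectory extrapolation, and week-wise log-binomial
    relative-risk estimation. A synthetic-cohort generator emulating archetype
    pain trajectories with binomial weekly counts makes the whole pipeline
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
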