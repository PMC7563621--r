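Package: stoptrace
Title: Stop-Signal Task Simulation and Time-Series State-Space SSRT Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the tracking stop-signal task (SST): an independent
    horse-race-model simulator with ex-Gaussian go and stop finish times and a
    1-up/1-down stop-signal-delay staircase; classical stop-signal reaction
    time (SSRT) estimators (Logan 1994 integration, cluster-Weighted, and
    Mixture indices based on the type of the preceding trial); and a
    time-series SSRT estimator that fits a missing-data linear-Gaussian
    state-space model to the trial-by-trial (GORT, SRRT, SSD) series by EM
    with Kalman smoothing and reads the SSRT off the smoothed go-RT channel.
    Includes paired and two-sample comparison helpers, cohort sweep tables,
    tidiers, and plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
VignetteBuilder: knitr
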