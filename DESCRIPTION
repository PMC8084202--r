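Package: mrtau
Title: Intrinsic Timescales from Subsampled Activity by Multi-Step Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the intrinsic timescale (autocorrelation time) of
    trial-structured activity time series by multi-step regression, a method
    that is invariant to spatial subsampling. Includes a driven
    branching-process simulator with binomial subsampling for ground-truth
    data, two estimators of lagged correlation coefficients (trial-separated
    and stationary-mean), nonlinear least-squares fitting of exponential,
    exponential-with-offset and damped-oscillation autocorrelation models,
    trial-level bootstrap confidence intervals, and closed-form predictions
    of the short-trial estimation bias.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    grDevices,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    minpack.lm,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr,
    patchwork,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
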