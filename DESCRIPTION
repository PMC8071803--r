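Package: patchseg
Title: Model-Free Multiscale Idealization of Single-Channel Patchclamp Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Idealization of single-channel patchclamp conductance recordings by
    model-free multiscale change-point methods that account explicitly for the
    analogue low-pass Bessel filter of the measurement device. Provides truncated
    Bessel kernels with exact autocorrelation, simulation of filtered traces with
    homogeneous or heterogeneous coloured Gaussian noise, Monte-Carlo calibrated
    multiscale detection with family-wise error control on scales above the filter
    length, short-event detection at and below the filter length, filter-aware
    local deconvolution of change times and conductance levels on a continuous
    time grid, and downstream conductance-level analysis (event and amplitude
    histograms, half-sample-mode level estimation, level assignment and merging,
    dwell-time extraction with truncated exponential fits).
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
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
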