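Package: fnirscast
Title: Reference-Free Physiological Noise Filtering for fNIRS via Wavelet
    Decomposition and Recurrent Forecasting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Removes physiological noise (cardiac, respiratory, Mayer-wave
    and very-low-frequency oscillations) from functional near-infrared
    spectroscopy (fNIRS) hemodynamic signals without a task-response
    reference. Resting-state data are decomposed with the maximal overlap
    discrete wavelet transform (MODWT); long short-term memory (LSTM)
    forecasters are trained on the low-frequency wavelet components and
    predict them into the task window, where the predictions are subtracted
    from the measured signal. Includes a labelled synthetic HbO signal
    generator (autoregressive baseline plus band-limited physiological
    oscillations and an optional two-gamma hemodynamic response), error
    metrics with group comparison statistics, and an experiment runner for
    the full validation protocol.
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
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
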