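Package: aadkit
Title: Auditory Attention Decoding from EEG by Stimulus Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditory attention decoding (AAD) in the two-competing-
    speaker paradigm. Implements the linear backward (stimulus-reconstruction)
    model: ridge regression of time-lagged multichannel EEG onto the attended
    speech envelope, evaluated offline with leave-one-out cross-validation and
    in a simulated real-time loop with a sliding window and exponential-moving-
    average smoothing of envelope correlations. Includes the full preprocessing
    chain (common-average re-referencing, band-pass filtering, resampling,
    z-scoring, Hilbert-envelope extraction), binomial chance levels, temporal
    sensitivity to spatial attention switches, and a forward-model synthetic
    EEG generator so the entire pipeline can be exercised without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    Matrix,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
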