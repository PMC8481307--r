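Package: brainprint
Title: Neurophysiological Fingerprinting from ROI Timeseries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Differentiates individuals from electrophysiological recordings
    summarized as region-of-interest (ROI) timeseries. Implements the two
    standard MEG fingerprinting feature sets (band-limited amplitude-envelope
    correlation connectomes and Welch power-spectral-density profiles),
    correlational identification across dataset pairs with per-participant
    differentiability scores, feature-level reliability metrics (intraclass
    correlation, group consistency, differential power), recording-artifact
    confound checks, and partial-least-squares correlation relating neural
    features to demographics with permutation and bootstrap inference. A
    synthetic cohort generator with planted subject structure supports
    end-to-end validation without access-controlled recordings.
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
    utils,
    withr,
    yaml
Suggests:
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
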