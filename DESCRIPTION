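Package: orienc
Title: Fisher-Information Analysis of Orientation Estimation Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing sensory encoding from orientation
    estimation psychophysics. Estimates bias and variance of responses as a
    function of target orientation with sliding-window von Mises fits,
    extracts the square root of Fisher information through the Cramer-Rao
    bound under a tight-bound assumption, recovers the efficient-coding
    prior by normalization, fits a two-parameter (lambda, omega) model of
    encoding capacity and resource allocation to the observed bias, and
    performs bootstrap group inference. Includes an encoder-decoder observer
    simulator for generating synthetic cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    graphics,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
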