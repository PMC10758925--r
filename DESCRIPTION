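Package: ccmdi
Title: Causalized Convergent Cross-Mapping and Directed Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects linear and nonlinear, unidirectional and bidirectional
    causal coupling between time series via convergent cross-mapping (CCM)
    and its causalized variant (cCCM), in which nearest-neighbour search on
    the delay-embedded shadow manifold is restricted to strictly earlier
    time indices so that the future of one process cannot influence the
    past of the other. Also provides plugin estimators of directed
    information (DI) and mutual information on quantized sequences, the
    closed-form Gaussian bridge between cross-map skill and DI together
    with its affine-corrected fit and inversion, multivariate conditional
    cross-mapping with variance-reduction causality ratios, a Granger
    causality baseline, seeded simulation generators (coupled Gaussians,
    sinusoids, autoregressive pairs, noisy oscillators, coupled logistic
    maps, delay-memory systems, additive white Gaussian noise at stated
    SNR), and a network layer that builds directed causality matrices over
    many channels, scores node transmitter/receiver significance, and
    selects unidirectional pairs by thresholded directional differences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    jsonlite
Config/testthat/edition: 3
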