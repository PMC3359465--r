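Package: gatewalk
Title: Random-Walk Models of Ion-Channel Gate Dynamics with Long-Term Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete random-walk simulators of the activation-gate dynamics of
    large-conductance (BK) potassium channels, in which slow, synchronized
    fluctuations of the conformational-space boundaries (Model 1) or of a drift
    force on the reaction coordinate (Model 2) generate long-term memory in the
    open/closed dwell-time series. Includes the full analysis chain used to
    characterize such series: kernel-density and double-Gaussian threshold
    idealization of noisy single-channel current traces, dwell-time statistics
    and log-binned histograms, rescaled-range (R/S) Hurst analysis with shuffle
    controls, a composite relative-error functional with coordinate-descent
    model fitting, closed-form physical scale estimates (apparent diffusion
    coefficients, mass and volume ratios), and a synthetic patch-clamp trace
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    mclust,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
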