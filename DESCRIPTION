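Package: ecgmcm
Title: Monte Carlo Measurement Uncertainty Analysis for a Two-Stage ECG Amplifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Propagates probability distributions assigned to the components and
    input signals of a two-stage electrocardiogram (ECG) amplifier front-end
    through its measurement equation by the Monte Carlo method, and summarises
    the result as full, per-source and per-block uncertainty budgets (mean,
    standard deviation, expanded uncertainty and coverage interval at 95 %
    coverage probability). Includes an analytic first-order (GUM-style)
    propagation engine for cross-validation, design-variant analysis such as
    substituting 0.1 % tolerance resistors for 1 % ones, a synthetic ECG
    waveform generator, and signal utilities (detrending, zero-phase low-pass
    filtering, power spectra, spectrograms, baseline/noise parameter
    estimation) for characterising the baseline and noise inputs of the model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
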