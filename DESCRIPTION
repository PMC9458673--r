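Package: avprofiler
Title: Acceleration-Velocity Profiling and Performance Prediction from
    GNSS Velocity Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling in-situ acceleration-velocity (A-V) profiles
    of team-sport athletes from 10 Hz GNSS velocity traces, and for asking
    whether session-level tracking features predict them. Implements the full
    profiling pipeline (backward-difference acceleration, first-order
    Butterworth low-pass filtering, per-velocity-bin maximal acceleration,
    linear envelope fit above 3 m/s), softmax exponential-decay pooling of
    session features, ridge regression with univariate F-test feature
    selection, uni-modal time-series forecasting baselines (naive, drift,
    Theta, FourTheta, FFT) with ensemble averaging, and MAPE-based model
    comparison with paired bootstrap contrasts. A synthetic season generator
    with known ground-truth envelopes provides end-to-end validation with
    recoverable truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
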