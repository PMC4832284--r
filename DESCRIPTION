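Package: sfmp
Title: Matching Pursuit Estimation of Spontaneous Skin Conductance
    Fluctuations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates tonic sympathetic arousal from skin conductance
    recordings by sparse deconvolution. Spontaneous fluctuations (SF) are
    modelled as responses of a linear time-invariant peripheral system to
    compact sudomotor-nerve (SN) bursts; the recording is decomposed over an
    overcomplete dictionary of candidate SF waveforms by a nonnegative greedy
    matching-pursuit search, SF amplitudes are reestimated by multiple
    regression, and the number of above-threshold SF per minute is reported
    as the arousal estimate. Includes a burst-train simulator with a
    refractory period, a nearest-in-time benchmarking module, and
    GLM/log-Bayes-factor statistics for predictive-validity comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    signal,
    stats,
    utils
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
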