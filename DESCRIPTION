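Package: emgonset
Title: Unsupervised Muscle Activity Onset Detection from Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects muscle activity onsets and offsets in single-channel
    surface electromyogram (EMG) recordings with an unsupervised sequential
    Gaussian mixture model. The log power of each Mel-spaced frequency band
    is modelled by a two-component mixture (non-burst noise vs EMG burst)
    whose parameters are updated frame by frame with a forgetting factor
    under constraints that keep the burst component identifiable; per-band
    adaptive Bayes-optimal thresholds are combined by voting into
    onset/offset segments. Includes a band-limited Gaussian-process surface
    EMG simulator with controllable (possibly time-varying) signal-to-noise
    ratio, three reference detectors (amplitude threshold, Teager-Kaiser
    energy threshold, Bonato double threshold), and a latency evaluation
    harness for SNR sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
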