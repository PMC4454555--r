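# emgonset

Unsupervised muscle activity onset/offset detection for single-channel
surface electromyography (EMG), built around a **sequential Gaussian
mixture model** of per-band log power.

Surface EMG onset detection underlies gait analysis, myoelectric
prosthesis control and neuromuscular assessment. Conventional detectors
threshold an amplitude envelope against baseline-noise statistics, which
requires a known quiet baseline and degrades when the signal-to-noise
ratio (SNR) is low or changes over time. `emgonset` instead learns the
signal statistics unsupervised, online, per frequency band:

* the signal is framed (Hanning, 32 ms window / 14 ms hop) and reduced to
  eight Mel-spaced subband log-power envelopes
  `x̄ = 10·log10(mean |Y|²)`, median-smoothed;
* each band's envelope is modelled by a two-component Gaussian mixture —
  non-burst (noise) vs burst — whose parameters
  `{w_i, μ_i, κ_i}` are updated frame by frame with a forgetting factor
  `α = 0.99` under the constraints `μ1 ≥ μ0 + δ` (δ = 3.5 dB),
  `κ1 ≥ κ0`, `w1 ≥ ε` (ε = 0.03), which keep a "virtual" burst component
  alive through long quiet stretches;
* each band classifies with the Bayes-optimal threshold solving
  `w1·f1(θ) = w0·f0(θ)` and the bands vote; voted frames become
  onset/offset segments.

The package also provides the band-limited Gaussian-process surface EMG
simulator used to validate the detector (shaping filter
`H(s) = k·s·(2πf_h)² / ((s+2πf_l)(s+2πf_h)²)`, 80–120 Hz, with
SNR-controlled and time-varying noise), three reference detectors
(amplitude threshold, Teager–Kaiser energy, Bonato double threshold) and
a paired latency evaluation harness.

## Worked example

```r
library(emgonset)

tr    <- simulate_clean_emg(4, fs = 2000, bursts = burst_spec(1, 3), seed = 1)
noisy <- add_noise_for_snr(tr, snr_db = 10, seed = 2)
cond  <- condition_signal(noisy)          # 20-500 Hz, 6th-order Butterworth
res   <- detect(cond)
res
#> <detection_result> 284 frames x 8 bands, 1 segment(s)
#>  onset_s offset_s
#>    0.994    2.996
```

The simulated burst spans 1–3 s; the detector reports one segment with
onset 0.994 s and offset 2.996 s, i.e. an onset latency of 6 ms (under
half a frame hop). `res$prob_map` holds the frames × bands burst
presence probabilities, `res$thresholds` the adaptive per-band
thresholds in dB, and `res$votes` the per-frame vote counts (0–8). The
reference detectors agree on this easy trial:

```r
c(amp = amp_detect(cond), tkeo = tkeo_detect(cond), bonato = bonato_detect(cond))
#>    amp   tkeo bonato
#> 1.0285 1.0215 1.0010
```

A small paired sweep shows why the unsupervised model matters at low
SNR — at 2 dB the amplitude detector's threshold (3 SD of baseline
noise) is never reached, while the sequential GMM still detects:

```r
summarize_latency(snr_sweep(methods = c("sgmm", "amp"),
                            snr_db = c(20, 2), n_trials = 5, seed = 1))
#>   method snr_db n_trials mean_ms  se_ms n_missed
#> 1    amp     20        5     9.1  0.797        0
#> 2    amp      2        5      NA     NA        5
#> 3   sgmm     20        5    20.0  0.000        0
#> 4   sgmm      2        5   316.0 14.000        3
```

A command-line interface with `simulate`, `features`, `detect` and
`evaluate` subcommands is installed at
`system.file("cli", "emgonset.R", package = "emgonset")`; see the
methods vignette (`vignettes/emg-onset-detection.Rmd`) for the model,
parameter choices and known limitations.

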