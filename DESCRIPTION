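Package: swdkit
Title: Detection and Simulation of Spike-and-Wave Discharges in Rodent EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-feature detection of seizure-like spike-and-wave discharges
    (SWDs) in chronic rodent cortical EEG. Recordings are split into 10-minute
    segments, bandpass filtered (third-order Butterworth, 0.5-400 Hz) and cut
    into 500 ms epochs; four per-epoch features (inter-epoch amplitude
    correlation, root-mean-square amplitude, spike density, and the 20-50 Hz
    over 0.5-20 Hz band-power ratio) are thresholded jointly, and flagged
    epochs are merged into ranked seizure candidates with episode statistics.
    Includes a seeded synthetic-EEG generator (1/f background plus injected
    spike-and-wave events with known timing) for validating detection by
    parameter recovery, a 16-bit EDF reader/writer, and small behavioural and
    metabolic metrics (pre-pulse inhibition, resting metabolic rate, foot-slip
    normalisation, repetitive nose-poke runs, 120-s synaptic charge transfer).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
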