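---
title: "Multi-feature detection of spike-and-wave discharges: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-feature detection of spike-and-wave discharges: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swdkit)
```

## The problem

Chronic cortical EEG in mouse models of excitatory/inhibitory imbalance
shows brief seizure-like spike-and-wave discharges (SWDs): episodes of a
few seconds in which sharp spikes ride on a slow wave at a repetition
frequency of several hertz, recurring a few times per hour. The
detector's job is to reduce many hours of recording to a short ranked
list of candidate episodes; final classification as electrographic
seizure remains a human decision and is deliberately outside this
package's scope.

## The detection model

Detection is per channel and fully deterministic. A recording is divided
into 10-minute segments, each bandpass filtered with a third-order
Butterworth design (0.5–400 Hz) and cut into 500 ms non-overlapping
epochs. Four features are computed per epoch:

* **amplitude correlation** — lag-0 Pearson correlation between the
  epoch's sample vector and its successor's. An SWD at a 6 Hz
  fundamental repeats exactly three cycles per 500 ms epoch, so
  consecutive within-event epochs are nearly identical and correlate
  near 1, while background epochs decorrelate. The phrase "correlation
  between successive epochs" admits a sliding-lag reading; we adopt the
  simplest lag-0 interpretation and expose the sliding maximum as an
  alternative only through the low-level API, since lag-0 already
  separates cleanly on the synthetic benchmark.
* **RMS** — `sqrt(mean(x^2))` in µV, the epoch's average amplitude.
* **spike density** — local extrema whose absolute amplitude exceeds
  5 robust SDs of the parent *segment* (1.4826 × MAD, floored at
  10⁻⁹ × |median| for degenerate inputs), with a 30 ms refractory rule
  keeping the larger of two conflicting extrema, divided by the epoch
  length. No published spike criterion exists for this assay; the MAD
  base was chosen because the seizures themselves would inflate a
  non-robust SD and suppress the very spikes being counted. 5 SD and
  30 ms are conventional values for sharp-transient detection in rodent
  EEG at 2 kHz.
* **band-power ratio** — Hann-windowed periodogram power summed over
  bins whose centres fall in [20, 50) Hz, divided by power over
  [0.5, 20) Hz plus a guard of 10⁻¹² × total power. Half-open bands
  prevent the 20 Hz bin counting twice. With 500 ms epochs the bin
  spacing is 2 Hz, so the lower band effectively begins at 2 Hz; this is
  documented rather than "fixed" because the 0.5–2 Hz octave carries
  little discriminative power once the 0.5 Hz highpass has been applied.
  A difference mode `(upper − lower)/total` is available for users who
  prefer a bounded contrast.

An epoch is flagged when **all four** features strictly exceed their
thresholds. The conjunction is what gives the detector its specificity:
movement artefacts raise RMS but not rhythmicity; brief noise spikes
raise spike density but not the band ratio.

### Thresholds

No absolute threshold values generalise across animals, electrodes and
amplifier settings, so the default is *self-calibration per recording*:
for RMS, spike density and band ratio the threshold is
`median + 3 × 1.4826 × MAD` over all epochs of the recording (all
channels pooled), requiring at least 100 epochs. Robust statistics keep
the baseline estimate untouched by the seizures themselves as long as
they occupy a small fraction of the recording (at 3.3 episodes/hour ×
4 s they occupy ~0.4%). The amplitude correlation is thresholded at an
absolute 0.5, since it already lives on a fixed [−1, 1] scale and its
background distribution is centred at 0. A consequence worth stating:
with robust-z thresholds the candidate set is exactly invariant to a
pure gain change of the recording, which the test suite checks
bit-for-bit.

### Merging

Flagged epochs are merged into candidates: maximal runs, bridging
interior gaps of at most one unflagged epoch, discarded below 1 s total
duration. Reported episodes average ~4 s, i.e. ~8 epochs, so a
single-epoch dropout (a weak wave cycle) should not split an episode,
and isolated single flagged epochs (0.5 s) are below any plausible
episode duration. Both constants are configurable.

### Accuracy scoring

`evaluate_detection()` matches candidates to ground-truth intervals
one-to-one: a candidate is admissible for a truth event when its
midpoint lies within 2 s of the truth interval, and the maximum
one-to-one matching (augmenting-path bipartite matching) is used, so the
reported sensitivity and FDR never depend on processing order.
Sensitivity = matched truths / all truths; FDR = unmatched candidates /
all candidates (undefined when there are no candidates).

## The synthetic generator

The generator exists to provide ground truth, not to model mouse cortex
faithfully. It emulates:

* **background** — coloured Gaussian noise with a 1/f^α spectrum
  (α = 1 by default), scaled exactly to a target RMS (50 µV default),
  generated in 10-minute FFT chunks; optional mains-frequency sinusoid.
* **event arrivals** — homogeneous Poisson at 3.3 episodes/hour, the
  reported rate convention, with a 1 s minimum inter-event gap; event
  count can be pinned for controlled benchmarks.
* **durations** — normal with mean 4.1 s and SD 0.4 s (the reported
  episode statistics), truncated below at 2 s.
* **the SWD waveform** — a slow sinusoid at the 6 Hz fundamental plus
  one sharp biphasic transient per cycle (a Hann-windowed single sine
  cycle of width `1/(fundamental × n_harmonics)`, default 28 ms), with
  ~10% lognormal per-cycle amplitude jitter, 0.25 s raised-cosine tapers
  at both ends, scaled to 4 × background RMS by default. The biphasic
  (up-then-down-stroke) spike shape matters: it concentrates the spike
  train's harmonic energy near `fundamental × n_harmonics` ≈ 36 Hz
  rather than at the lowest harmonics, which is both what real EEG
  spikes look like after highpass filtering and what places the event's
  spectral signature in the 20–50 Hz band. The wave:spike amplitude
  proportion (0.7 : ~5 before normalisation) keeps the periodogram's
  dominant peak at the fundamental while the spikes dominate the
  morphology. The event amplitude relative to baseline is not a measured
  quantity anywhere; 4 × background RMS is this package's calibration
  choice for a clearly supra-threshold event, and it is the one
  generator constant a user should expect to revisit for harder
  benchmarks.

All randomness flows from one root seed through named substreams
(background / schedule / per-event waveform), so each component is
independently reproducible and the full simulate→detect pipeline is
byte-identical across runs with one seed.

What the generator does **not** emulate: state-dependent background
(sleep/wake spectra), movement and chewing artefacts, electrode drift,
inter-channel correlation (channels are independent), and focal
propagation delays. Passing the recovery benchmark therefore shows the
algorithm is correct and well-calibrated for its feature model, not that
these defaults transfer to any particular rig without threshold review.

## Numerical choices

* **Filter design and application.** The Butterworth bandpass is
  designed with `signal::butter`; at 0.5/400 Hz on a 2 kHz rate the
  transfer-function form is numerically clean (band-edge gains
  −3.0103 dB, DC gain 0, poles within the unit circle), which the test
  suite verifies against the analytic response. Zero-phase filtering is
  the default so candidate timestamps carry no group delay; it is
  implemented as a forward and a backward pass with odd-symmetric edge
  extension (2 s) and steady-state initial conditions on each pass, so
  the slow 0.5 Hz pole's transient stays inside the discarded padding
  and a constant input maps everywhere to the filter's exact DC gain.
  The two passes square the magnitude response (−6 dB at the band
  edges); a single-pass causal mode is available for a strictly literal
  reading of the acquisition description, which does not state phase
  handling.
* **Epoch grid.** Half-open intervals throughout, 0-based sample
  indexing, trailing partial epochs dropped; a final partial segment
  shorter than one epoch is dropped with a message, shorter-than-10-min
  but ≥ 0.5 s segments are processed. Segmentation is exactly invertible
  (concatenation reproduces the channel), which is tested.
* **Degenerate inputs.** Zero-variance epochs return correlation 0 with
  a `degenerate` flag; the final epoch of a segment copies the previous
  correlation and is flagged `amp_corr_copied`; MAD floors guard
  constant segments and constant feature columns.
* **EDF.** 16-bit EDF with 1 s records, symmetric digital range
  ±32767 so that 0 µV is an exact code, physical-min written as the
  negated physical-max string so the header range is exactly symmetric
  despite ASCII rounding. Round-trip error is bounded by the physical
  range / 2¹⁶ and tested against the coarser range / 2¹⁵ contract.

## Validation problem sizes

The test suite validates parameter recovery on ten seeded 2-hour
single-channel recordings at 2 kHz with eight injected events each
(mean sensitivity ≥ 0.85, mean FDR ≤ 0.15, mean |duration error| ≤ 1 s
required; the defaults achieve 1.00 / 0.00 / ~0.6 s), and specificity on
ten 1-hour background-only recordings (0 candidates required in ≥ 9).
Schedule calibration is checked over 500 simulated hours (rate and mean
duration within 5%). Two hours at a few episodes per hour mirrors the
daily recording sessions of the target assay; longer simulations change
nothing structurally since thresholds are medians over epochs.

## Known limitations

* Candidates are per channel; no cross-channel consensus or propagation
  analysis.
* The detector stops at ranked candidates with audit features; it does
  not classify seizure types, and single-epoch (< 1 s) events are below
  the merge rule's floor by design.
* The spike criterion and threshold scheme are this package's
  decisions where the assay description is silent (per-recording robust
  z; whether the original analysis used per-animal or global thresholds
  is unknown). Absolute-mode thresholds are provided for users who
  calibrate externally.
* The 120-s charge metric integrates |current − baseline| by the
  trapezoid rule; a signed mode exists because the sign convention of
  the source traces is not fixed by the assay description.
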