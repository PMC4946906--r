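# Synthetic rodent-EEG generator: coloured-noise background plus injected
# spike-and-wave discharges (SWDs) at known times. Provides ground truth for
# validating the detector by parameter recovery.

#' Background-activity parameters
#'
#' The background model is coloured Gaussian noise with a 1/f^alpha power
#' spectrum, scaled to a target RMS amplitude, optionally with additive
#' mains-frequency line noise.
#'
#' @param rms_amplitude target root-mean-square amplitude in microvolts.
#' @param spectral_exponent alpha of the 1/f^alpha spectrum, in \[0, 3\];
#'   1 approximates cortical surface EEG.
#' @param line_noise_amplitude peak amplitude (uV) of an optional mains
#'   sinusoid; 0 disables it.
#' @param line_frequency mains frequency in Hz.
#' @return list of class `background_params`.
#' @export
background_params <- function(rms_amplitude = 50, spectral_exponent = 1,
                              line_noise_amplitude = 0, line_frequency = 60) {
  stopifnot_scalar(rms_amplitude, "rms_amplitude", nonneg = TRUE)
  stopifnot_scalar(spectral_exponent, "spectral_exponent")
  if (spectral_exponent < 0 || spectral_exponent > 3)
    stop("'spectral_exponent' must lie in [0, 3]", call. = FALSE)
  stopifnot_scalar(line_noise_amplitude, "line_noise_amplitude", nonneg = TRUE)
  stopifnot_scalar(line_frequency, "line_frequency", positive = TRUE)
  structure(list(rms_amplitude = rms_amplitude,
                 spectral_exponent = spectral_exponent,
                 line_noise_amplitude = line_noise_amplitude,
                 line_frequency = line_frequency),
            class = "background_params")
}

#' Spike-and-wave discharge parameters
#'
#' Generative model of a seizure-like SWD: events arrive as a homogeneous
#' Poisson process at `rate` episodes/hour; durations are normal, truncated
#' below at `duration_min`; the waveform is a slow wave at the fundamental
#' frequency summed with a sharp raised-cosine spike train (one spike per
#' cycle), which places harmonic power in the 20-50 Hz band. Defaults follow
#' the episode statistics of chronic cortical recordings in MeCP2-deficient
#' mice: about 3.3 episodes/hour, 4.1 s mean duration.
#'
#' @param rate episodes per hour (>= 0).
#' @param duration_mean,duration_sd,duration_min seconds; the duration
#'   distribution is N(mean, sd^2) truncated at `duration_min`.
#' @param fundamental spike-wave repetition frequency in Hz (< 20 so the
#'   harmonics fall in the 20-50 Hz band).
#' @param spike_amplitude_ratio event RMS as a multiple of the background
#'   RMS. Not a measured quantity; a calibration knob of the simulator.
#' @param n_harmonics controls spike sharpness: the raised-cosine pulse
#'   width is `1 / (fundamental * n_harmonics)`, so harmonic content
#'   extends to roughly `n_harmonics * fundamental` Hz.
#' @return list of class `swd_params`.
#' @export
swd_params <- function(rate = 3.3, duration_mean = 4.1, duration_sd = 0.4,
                       duration_min = 2, fundamental = 6,
                       spike_amplitude_ratio = 4, n_harmonics = 6) {
  stopifnot_scalar(rate, "rate", nonneg = TRUE)
  stopifnot_scalar(duration_min, "duration_min", positive = TRUE)
  stopifnot_scalar(duration_mean, "duration_mean", positive = TRUE)
  stopifnot_scalar(duration_sd, "duration_sd", nonneg = TRUE)
  if (duration_mean < duration_min)
    stop("'duration_mean' must be >= 'duration_min'", call. = FALSE)
  stopifnot_scalar(fundamental, "fundamental", positive = TRUE)
  if (fundamental >= 20)
    stop("'fundamental' must be < 20 Hz so harmonics fall in the upper band",
         call. = FALSE)
  stopifnot_scalar(spike_amplitude_ratio, "spike_amplitude_ratio",
                   positive = TRUE)
  stopifnot_scalar(n_harmonics, "n_harmonics", positive = TRUE)
  structure(list(rate = rate, duration_mean = duration_mean,
                 duration_sd = duration_sd, duration_min = duration_min,
                 fundamental = fundamental,
                 spike_amplitude_ratio = spike_amplitude_ratio,
                 n_harmonics = n_harmonics),
            class = "swd_params")
}

#' Simulation configuration
#'
#' @param duration recording length in seconds.
#' @param sampling_rate Hz; default 2000 matches chronic rodent video-EEG
#'   acquisition.
#' @param n_channels number of channels.
#' @param channel_labels optional channel names.
#' @param seed root integer seed; all randomness (background, event
#'   schedule, waveform jitter) flows from it through named substreams.
#' @param background a [background_params()] object.
#' @param swd a [swd_params()] object.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(duration, sampling_rate = 2000, n_channels = 1,
                       channel_labels = NULL, seed = 0,
                       background = background_params(),
                       swd = swd_params()) {
  stopifnot_scalar(duration, "duration", positive = TRUE)
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  stopifnot_scalar(n_channels, "n_channels", positive = TRUE)
  stopifnot(inherits(background, "background_params"),
            inherits(swd, "swd_params"))
  # keep everything below Nyquist: harmonic content tops out near
  # fundamental * n_harmonics, line noise at the mains frequency
  top <- max(swd$fundamental * swd$n_harmonics, background$line_frequency)
  if (sampling_rate <= 2 * top)
    stop("'sampling_rate' must exceed twice the highest synthesised frequency",
         call. = FALSE)
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(n_channels))
  structure(list(duration = duration, sampling_rate = sampling_rate,
                 n_channels = as.integer(n_channels),
                 channel_labels = as.character(channel_labels),
                 seed = as.integer(seed),
                 background = background, swd = swd),
            class = "sim_config")
}

# One chunk of 1/f^alpha Gaussian noise, exact-RMS scaled. FFT shaping:
# white complex spectrum multiplied by f^(-alpha/2), DC removed.
colored_noise_chunk <- function(n, sampling_rate, alpha, rms) {
  if (rms == 0) return(numeric(n))
  x <- stats::rnorm(n)
  if (alpha > 0) {
    f <- seq_len(n) - 1
    f <- pmin(f, n - f) * (sampling_rate / n)
    shape <- c(0, f[-1]^(-alpha / 2))
    x <- Re(stats::fft(stats::fft(x) * shape, inverse = TRUE)) / n
  } else {
    x <- x - mean(x)
  }
  x * (rms / sqrt(mean(x^2)))
}

#' Generate background EEG
#'
#' Coloured-noise background for every channel of the configuration, with
#' no events injected. Channels are independent. Noise is generated in
#' 10-minute chunks, each scaled exactly to the target RMS.
#'
#' @param config a [sim_config()].
#' @return an [eeg_recording()].
#' @examples
#' cfg <- sim_config(duration = 10, seed = 1)
#' bg <- generate_background(cfg)
#' sqrt(mean(bg$samples^2))  # ~ 50 uV
#' @export
generate_background <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  bp <- config$background
  chunk <- min(n, round(600 * fs))
  with_seed(substream_seed(config$seed, "background"), {
    samples <- matrix(0, nrow = config$n_channels, ncol = n)
    for (ch in seq_len(config$n_channels)) {
      pos <- 1L
      while (pos <= n) {
        len <- min(chunk, n - pos + 1L)
        samples[ch, pos:(pos + len - 1L)] <-
          colored_noise_chunk(len, fs, bp$spectral_exponent, bp$rms_amplitude)
        pos <- pos + len
      }
      if (bp$line_noise_amplitude > 0) {
        t <- (seq_len(n) - 1) / fs
        samples[ch, ] <- samples[ch, ] +
          bp$line_noise_amplitude * sin(2 * pi * bp$line_frequency * t)
      }
    }
    eeg_recording(samples, fs, config$channel_labels)
  })
}

#' Sample a spike-and-wave event schedule
#'
#' Homogeneous Poisson arrivals at `swd$rate` episodes/hour over the given
#' duration; durations drawn from N(duration_mean, duration_sd^2) truncated
#' below at `duration_min`. Events are placed so that they lie fully inside
#' the recording and are separated by at least 1 s; each placement is
#' redrawn (up to 1000 times) on conflict so the Poisson count is
#' preserved.
#'
#' @param swd a [swd_params()].
#' @param duration recording duration in seconds.
#' @param seed integer seed.
#' @param n_events optional fixed event count overriding the Poisson draw
#'   (used for controlled benchmarks).
#' @return data.frame with columns `start`, `duration` (seconds), sorted by
#'   start; zero rows when the rate is 0.
#' @export
sample_event_schedule <- function(swd, duration, seed = 0, n_events = NULL) {
  stopifnot(inherits(swd, "swd_params"))
  stopifnot_scalar(duration, "duration", positive = TRUE)
  gap <- 1  # minimum inter-event spacing, s
  with_seed(substream_seed(seed, "schedule"), {
    n <- if (is.null(n_events)) stats::rpois(1, swd$rate * duration / 3600)
         else as.integer(n_events)
    out <- data.frame(start = numeric(0), duration = numeric(0))
    if (n == 0) return(out)
    durs <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        d <- stats::rnorm(1, swd$duration_mean, swd$duration_sd)
        if (d >= swd$duration_min) break
      }
      durs[i] <- d
    }
    starts <- rep(NA_real_, n)
    placed <- 0L
    for (i in seq_len(n)) {
      if (durs[i] >= duration) next  # cannot fit; drop
      for (try in seq_len(1000L)) {
        s <- stats::runif(1, 0, duration - durs[i])
        # conflict iff intervals padded by `gap` overlap an accepted event
        if (placed > 0L) {
          ps <- starts[!is.na(starts)]
          pd <- durs[!is.na(starts)]
          ok <- all(s + durs[i] + gap <= ps | ps + pd + gap <= s)
        } else ok <- TRUE
        if (ok) { placed <- placed + 1L; starts[i] <- s; break }
      }
    }
    keep <- !is.na(starts)
    out <- data.frame(start = starts[keep], duration = durs[keep])
    out[order(out$start), , drop = FALSE]
  })
}

#' Synthesise a single spike-and-wave discharge waveform
#'
#' Sum of a slow sinusoid at the fundamental frequency and a sharp
#' biphasic spike train (one Hann-windowed sine transient per cycle, the
#' shape of an EEG spike with its fast up- and down-stroke), with mild
#' per-cycle amplitude jitter, tapered by a 0.25 s raised-cosine ramp at
#' both ends and scaled to unit RMS. The dominant periodogram peak sits at
#' the fundamental (the slow wave); the biphasic spikes concentrate their
#' harmonic power near `1 / pulse width`, i.e. in the 20-50 Hz band at the
#' defaults.
#'
#' @param duration waveform length in seconds (>= one cycle).
#' @param swd a [swd_params()].
#' @param sampling_rate Hz.
#' @param seed integer seed (per-cycle jitter).
#' @return numeric vector of `round(duration * sampling_rate)` samples with
#'   unit RMS.
#' @export
synthesize_swd <- function(duration, swd, sampling_rate, seed = 0) {
  stopifnot(inherits(swd, "swd_params"))
  stopifnot_scalar(duration, "duration", positive = TRUE)
  if (duration < 1 / swd$fundamental)
    stop("'duration' must cover at least one cycle of the fundamental",
         call. = FALSE)
  n <- round(duration * sampling_rate)
  t <- (seq_len(n) - 1) / sampling_rate
  f0 <- swd$fundamental
  with_seed(substream_seed(seed, "waveform"), {
    wave <- 0.7 * sin(2 * pi * f0 * t)
    # biphasic spikes: Hann-windowed single sine cycle of width
    # 1/(f0 * n_harmonics), one per fundamental cycle, spectral energy
    # concentrated near f0 * n_harmonics; amplitude jittered ~10% around
    # about seven times the wave amplitude (spikes dominate the morphology)
    tau <- 1 / (f0 * swd$n_harmonics)
    centers <- seq(1 / (2 * f0), duration - 1 / (2 * f0), by = 1 / f0)
    spikes <- numeric(n)
    amps <- 5 * exp(stats::rnorm(length(centers), 0, 0.1))
    for (k in seq_along(centers)) {
      idx <- which(abs(t - centers[k]) <= tau / 2)
      u <- (t[idx] - centers[k]) / tau
      spikes[idx] <- spikes[idx] +
        amps[k] * sin(2 * pi * u) * 0.5 * (1 + cos(2 * pi * u))
    }
    x <- wave + spikes
    x <- x - mean(x)
    ramp <- min(0.25, duration / 4)
    nr <- round(ramp * sampling_rate)
    if (nr > 1) {
      w <- 0.5 * (1 - cos(pi * (seq_len(nr) - 1) / (nr - 1)))
      x[seq_len(nr)] <- x[seq_len(nr)] * w
      x[(n - nr + 1):n] <- x[(n - nr + 1):n] * rev(w)
    }
    x / sqrt(mean(x^2))
  })
}

#' Inject scheduled events into a recording
#'
#' Adds the SWD waveform, scaled to `spike_amplitude_ratio` times the
#' background RMS target, to every channel over each scheduled interval.
#' Samples outside the scheduled intervals are untouched.
#'
#' @param recording an [eeg_recording()].
#' @param schedule data.frame with `start`, `duration` columns (seconds),
#'   as from [sample_event_schedule()].
#' @param swd a [swd_params()].
#' @param seed integer seed for waveform jitter.
#' @param amplitude absolute event RMS in uV; by default
#'   `swd$spike_amplitude_ratio * rms(recording)` is used.
#' @return list with elements `recording` (events added) and `events`
#'   (an [event_table()] mirroring the schedule, one row per channel and
#'   event, labelled `"swd"`).
#' @export
inject_events <- function(recording, schedule, swd, seed = 0,
                          amplitude = NULL) {
  stopifnot(inherits(recording, "eeg_recording"),
            inherits(swd, "swd_params"))
  dur <- rec_duration(recording)
  if (nrow(schedule) > 0 && any(schedule$start < 0 |
                                schedule$start + schedule$duration > dur))
    stop("scheduled event extends beyond the recording", call. = FALSE)
  fs <- recording$sampling_rate
  if (is.null(amplitude))
    amplitude <- swd$spike_amplitude_ratio * sqrt(mean(recording$samples^2))
  out <- recording
  for (i in seq_len(nrow(schedule))) {
    w <- synthesize_swd(schedule$duration[i], swd, fs,
                        seed = substream_seed(seed, paste0("event", i)))
    i0 <- round(schedule$start[i] * fs) + 1L
    idx <- i0:(i0 + length(w) - 1L)
    out$samples[, idx] <- sweep(out$samples[, idx, drop = FALSE], 2,
                                amplitude * w, "+")
  }
  events <- do.call(rbind, lapply(recording$channel_labels, function(ch) {
    if (nrow(schedule) == 0) return(NULL)
    data.frame(channel = ch, start = schedule$start,
               end = schedule$start + schedule$duration, label = "swd",
               stringsAsFactors = FALSE)
  }))
  if (is.null(events))
    events <- event_table()
  else
    events <- events[order(events$channel, events$start), , drop = FALSE]
  list(recording = out, events = events)
}

#' Simulate a full synthetic EEG recording with ground truth
#'
#' Convenience wrapper: background, event schedule, and injection, all
#' driven from the configuration's root seed.
#'
#' @param config a [sim_config()].
#' @param n_events optional fixed event count (see
#'   [sample_event_schedule()]).
#' @return list with `recording` (an [eeg_recording()]) and `truth`
#'   (an [event_table()] of injected events).
#' @examples
#' sim <- simulate_eeg(sim_config(duration = 60, seed = 7), n_events = 1)
#' sim$truth
#' @export
simulate_eeg <- function(config, n_events = NULL) {
  stopifnot(inherits(config, "sim_config"))
  bg <- generate_background(config)
  sched <- sample_event_schedule(config$swd, config$duration,
                                 seed = config$seed, n_events = n_events)
  inj <- inject_events(bg, sched, config$swd, seed = config$seed,
                       amplitude = config$swd$spike_amplitude_ratio *
                         config$background$rms_amplitude)
  list(recording = inj$recording, truth = inj$events)
}
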