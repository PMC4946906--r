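# Segmentation into 10-minute blocks and Butterworth bandpass filtering.

#' Bandpass filter specification
#'
#' Third-order Butterworth bandpass, 0.5-400 Hz by default, matching the
#' filtering applied to each 10-minute EEG segment before feature
#' extraction. Zero-phase (forward-backward) application is the default so
#' that candidate timestamps are not skewed by group delay; note that the
#' two passes square the magnitude response (-6 dB at the band edges).
#'
#' @param order filter order (default 3).
#' @param low_cutoff,high_cutoff band edges in Hz (defaults 0.5 and 400).
#' @param zero_phase logical; `TRUE` applies the filter forward and
#'   backward ([signal::filtfilt()]), `FALSE` gives a single causal pass.
#' @return list of class `filter_spec`.
#' @export
filter_spec <- function(order = 3, low_cutoff = 0.5, high_cutoff = 400,
                        zero_phase = TRUE) {
  stopifnot_scalar(order, "order", positive = TRUE)
  stopifnot_scalar(low_cutoff, "low_cutoff", positive = TRUE)
  stopifnot_scalar(high_cutoff, "high_cutoff", positive = TRUE)
  if (low_cutoff >= high_cutoff)
    stop("'low_cutoff' must be below 'high_cutoff'", call. = FALSE)
  structure(list(order = as.integer(order), low_cutoff = low_cutoff,
                 high_cutoff = high_cutoff, zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

butter_coefs <- function(spec, sampling_rate) {
  if (spec$high_cutoff >= sampling_rate / 2)
    stop("'high_cutoff' must be below the Nyquist frequency", call. = FALSE)
  signal::butter(spec$order,
                 c(spec$low_cutoff, spec$high_cutoff) / (sampling_rate / 2),
                 type = "pass")
}

# Zero-phase filtering with odd-symmetric edge extension and steady-state
# initial conditions on both passes, so that edge transients of the slow
# 0.5 Hz pole stay inside the (discarded) padding and constant inputs map
# to the filter's exact DC gain everywhere.
filtfilt_ss <- function(bt, x, sampling_rate) {
  b <- bt$b; a <- bt$a
  m <- max(length(a), length(b)) - 1L
  dc <- sum(b) / sum(a)
  one_pass <- function(v) {
    as.numeric(signal::filter(b, a, v, init.x = rep(v[1L], m),
                              init.y = rep(v[1L] * dc, m)))
  }
  pad <- min(length(x) - 1L, round(2 * sampling_rate))
  if (pad > 0) {
    front <- 2 * x[1L] - x[(pad + 1L):2L]
    back <- 2 * x[length(x)] - x[(length(x) - 1L):(length(x) - pad)]
    ext <- c(front, x, back)
  } else ext <- x
  y <- one_pass(ext)
  y <- rev(one_pass(rev(y)))
  if (pad > 0) y <- y[(pad + 1L):(pad + length(x))]
  y
}

#' Split a channel into fixed-length segments
#'
#' Divides one channel of a recording into consecutive segments (10 minutes
#' by default). The final segment may be shorter; a trailing remainder
#' shorter than `min_length` (one 500 ms epoch by default) is dropped with
#' a message, since it cannot contribute a single analysis epoch.
#'
#' @param recording an [eeg_recording()].
#' @param channel channel label or index (default first channel).
#' @param segment_length nominal segment length in seconds (default 600).
#' @param min_length minimum final-segment length kept, seconds.
#' @return list of `segment` objects: lists with `channel`, `index`
#'   (0-based), `offset` (seconds from recording start), `samples`,
#'   `sampling_rate`.
#' @examples
#' rec <- eeg_recording(sin(seq_len(2000)), 2000)
#' length(segment_signal(rec, segment_length = 0.5))
#' @export
segment_signal <- function(recording, channel = 1, segment_length = 600,
                           min_length = 0.5) {
  stopifnot(inherits(recording, "eeg_recording"))
  stopifnot_scalar(segment_length, "segment_length", positive = TRUE)
  if (is.character(channel))
    channel <- match(channel, recording$channel_labels)
  if (is.na(channel) || channel < 1 || channel > nrow(recording$samples))
    stop("unknown channel", call. = FALSE)
  x <- recording$samples[channel, ]
  fs <- recording$sampling_rate
  seg_n <- round(segment_length * fs)
  starts <- seq(1L, length(x), by = seg_n)
  segs <- vector("list", length(starts))
  kept <- 0L
  for (i in seq_along(starts)) {
    idx <- starts[i]:min(starts[i] + seg_n - 1L, length(x))
    if (length(idx) < round(min_length * fs)) {
      message(sprintf("dropping final partial segment of %.3f s (< %g s)",
                      length(idx) / fs, min_length))
      break
    }
    kept <- kept + 1L
    segs[[kept]] <- structure(
      list(channel = recording$channel_labels[channel], index = i - 1L,
           offset = (starts[i] - 1L) / fs, samples = x[idx],
           sampling_rate = fs),
      class = "eeg_segment")
  }
  segs[seq_len(kept)]
}

#' Bandpass-filter a segment
#'
#' Applies the Butterworth bandpass of the specification to a segment (or
#' bare numeric vector). Zero-phase mode filters forward and backward.
#'
#' @param segment an `eeg_segment` from [segment_signal()], or a numeric
#'   vector (then `sampling_rate` must be given).
#' @param spec a [filter_spec()].
#' @param sampling_rate required when `segment` is a bare vector.
#' @return the segment with filtered samples (same length), or a filtered
#'   numeric vector.
#' @export
bandpass <- function(segment, spec = filter_spec(), sampling_rate = NULL) {
  if (is.numeric(segment)) {
    stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
    bt <- butter_coefs(spec, sampling_rate)
    return(if (spec$zero_phase) filtfilt_ss(bt, segment, sampling_rate)
           else as.numeric(signal::filter(bt, segment)))
  }
  stopifnot(inherits(segment, "eeg_segment"))
  segment$samples <- bandpass(segment$samples, spec,
                              sampling_rate = segment$sampling_rate)
  segment
}

#' Frequency response of the designed bandpass filter
#'
#' Evaluates the complex frequency response of the digital Butterworth
#' filter at the requested frequencies; useful for verifying the -3 dB
#' band edges. For zero-phase application the effective magnitude is the
#' square of the single-pass magnitude returned here.
#'
#' @param spec a [filter_spec()].
#' @param sampling_rate Hz.
#' @param freqs frequencies (Hz) at which to evaluate.
#' @return numeric vector of single-pass magnitude responses.
#' @examples
#' 20 * log10(filter_response(filter_spec(), 2000, c(0.5, 400)))  # ~ -3 dB
#' @export
filter_response <- function(spec, sampling_rate, freqs) {
  bt <- butter_coefs(spec, sampling_rate)
  vapply(freqs, function(f) {
    z <- exp(-1i * 2 * pi * f / sampling_rate)
    k <- seq_along(bt$b) - 1
    Mod(sum(bt$b * z^k) / sum(bt$a * z^k))
  }, numeric(1))
}
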