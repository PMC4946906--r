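# Per-epoch detection features: inter-epoch amplitude correlation, RMS,
# spike density, and the 20-50 / 0.5-20 Hz band-power ratio.

#' Spike-detection criteria
#'
#' A spike is a local extremum whose absolute amplitude exceeds
#' `threshold_multiplier` times the robust SD (1.4826 x MAD) of the parent
#' filtered segment, with a refractory spacing: of two extrema closer than
#' `refractory` seconds, only the larger is kept.
#'
#' @param threshold_multiplier multiple of the segment's robust SD
#'   (default 5).
#' @param refractory minimum spacing between counted spikes, seconds
#'   (default 0.03).
#' @return list of class `spike_criteria`.
#' @export
spike_criteria <- function(threshold_multiplier = 5, refractory = 0.03) {
  stopifnot_scalar(threshold_multiplier, "threshold_multiplier",
                   positive = TRUE)
  stopifnot_scalar(refractory, "refractory", nonneg = TRUE)
  structure(list(threshold_multiplier = threshold_multiplier,
                 refractory = refractory),
            class = "spike_criteria")
}

#' Cut a signal into non-overlapping epochs
#'
#' @param x numeric vector (a filtered segment's samples).
#' @param sampling_rate Hz.
#' @param epoch_length epoch length in seconds (default 0.5).
#' @return a matrix with one column per epoch (`epoch_length *
#'   sampling_rate` rows); the trailing partial window is discarded. A
#'   signal shorter than one epoch yields a zero-column matrix with a
#'   warning.
#' @examples
#' ncol(epoch_matrix(rnorm(2500), 2000))  # 2 epochs, 500 samples dropped
#' @export
epoch_matrix <- function(x, sampling_rate, epoch_length = 0.5) {
  n_ep <- round(epoch_length * sampling_rate)
  k <- floor(length(x) / n_ep)
  if (k == 0) {
    warning("signal shorter than one epoch; no epochs produced")
    return(matrix(numeric(0), nrow = n_ep, ncol = 0))
  }
  matrix(x[seq_len(k * n_ep)], nrow = n_ep)
}

#' Amplitude correlation between two epochs
#'
#' Lag-0 Pearson correlation between the sample vectors of two
#' equal-length epochs; in the pipeline the second epoch is the successor
#' of the first, so rhythmic discharges spanning consecutive epochs score
#' near 1. If either epoch has zero variance the correlation is undefined
#' and 0 is returned with attribute `degenerate = TRUE`.
#'
#' @param a,b numeric vectors of equal length.
#' @return correlation in \[-1, 1\].
#' @export
amplitude_correlation <- function(a, b) {
  if (length(a) != length(b))
    stop("epochs must have equal length", call. = FALSE)
  if (stats::var(a) == 0 || stats::var(b) == 0)
    return(structure(0, degenerate = TRUE))
  stats::cor(a, b)
}

#' Root-mean-square amplitude of an epoch
#'
#' @param x numeric vector.
#' @return `sqrt(mean(x^2))`, in the units of `x` (uV in the pipeline).
#' @export
epoch_rms <- function(x) {
  if (length(x) == 0) stop("empty epoch", call. = FALSE)
  sqrt(mean(x^2))
}

# Local extrema (peaks and troughs) of a vector: indices where the first
# difference changes sign. Plateau samples count once (at the entry edge).
local_extrema <- function(x) {
  d <- sign(diff(x))
  # carry the last non-zero slope through plateaus (vectorised LOCF)
  nz <- which(d != 0)
  if (length(nz) == 0) return(integer(0))
  pos <- findInterval(seq_along(d), nz)
  pos[pos == 0L] <- 1L
  d2 <- d[nz][pos]
  which(diff(d2) != 0) + 1L
}

# Refractory enforcement: greedy left-to-right sweep keeping the larger of
# two conflicting extrema.
enforce_refractory <- function(idx, amp, min_gap) {
  if (length(idx) <= 1L || min_gap <= 0) return(idx)
  keep <- idx[1L]; keep_amp <- amp[1L]
  out <- integer(0); out_amp <- numeric(0)
  for (i in seq_along(idx)[-1L]) {
    if (idx[i] - keep < min_gap) {
      if (amp[i] > keep_amp) { keep <- idx[i]; keep_amp <- amp[i] }
    } else {
      out <- c(out, keep); out_amp <- c(out_amp, keep_amp)
      keep <- idx[i]; keep_amp <- amp[i]
    }
  }
  c(out, keep)
}

#' Spike density of an epoch
#'
#' Counts local extrema whose absolute amplitude exceeds
#' `criteria$threshold_multiplier` times the supplied robust scale
#' (precomputed over the epoch's parent filtered segment), enforces the
#' refractory spacing, and normalises by the epoch length.
#'
#' @param x numeric vector (one epoch).
#' @param sampling_rate Hz.
#' @param segment_scale robust SD of the parent filtered segment, uV
#'   (see [robust_segment_scale()]).
#' @param criteria a [spike_criteria()].
#' @return spikes per second.
#' @export
spike_density <- function(x, sampling_rate, segment_scale,
                          criteria = spike_criteria()) {
  stopifnot(inherits(criteria, "spike_criteria"))
  if (!is.numeric(segment_scale) || segment_scale <= 0)
    stop("'segment_scale' must be positive", call. = FALSE)
  thr <- criteria$threshold_multiplier * segment_scale
  ext <- local_extrema(x)
  ext <- ext[abs(x[ext]) > thr]
  ext <- enforce_refractory(ext, abs(x[ext]),
                            criteria$refractory * sampling_rate)
  length(ext) / (length(x) / sampling_rate)
}

#' Robust amplitude scale of a filtered segment
#'
#' 1.4826 x median absolute deviation of the segment samples: the spread
#' estimate spikes are measured against. MAD-based so that the seizures
#' themselves do not inflate the baseline.
#'
#' @param x numeric vector (a filtered segment's samples).
#' @return robust SD in the units of `x`.
#' @export
robust_segment_scale <- function(x) robust_scale(x)

#' Band-power ratio of an epoch
#'
#' Power in the upper band (20-50 Hz) contrasted with the lower band
#' (0.5-20 Hz), from a Hann-windowed periodogram. Band membership is by
#' bin-centre frequency over half-open intervals `[low, high)`, so the
#' 20 Hz bin belongs to the upper band only. A guard of `1e-12 x` total
#' power in the denominator protects against division by zero. With 500 ms
#' epochs the bin spacing is 2 Hz, so the lower band effectively starts at
#' 2 Hz.
#'
#' @param x numeric vector (one epoch).
#' @param sampling_rate Hz.
#' @param lower,upper numeric length-2 band edges in Hz.
#' @param mode `"ratio"` (default) returns upper/lower; `"difference"`
#'   returns upper - lower (both normalised by total power).
#' @return dimensionless ratio >= 0 (or a difference in \[-1, 1\] for
#'   `mode = "difference"`).
#' @export
band_power_ratio <- function(x, sampling_rate, lower = c(0.5, 20),
                             upper = c(20, 50), mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))  # Hann
  p <- Mod(stats::fft(x * w))^2
  nf <- floor(n / 2)
  freqs <- (seq_len(nf) ) * sampling_rate / n  # positive-frequency bins
  p <- p[2:(nf + 1L)]
  lo <- sum(p[freqs >= lower[1] & freqs < lower[2]])
  hi <- sum(p[freqs >= upper[1] & freqs < upper[2]])
  if (mode == "difference") {
    tot <- sum(p)
    if (tot == 0) return(0)
    return((hi - lo) / tot)
  }
  hi / (lo + 1e-12 * sum(p))
}

#' Per-epoch feature table for one filtered segment
#'
#' Computes the four detection features for every 500 ms epoch of a
#' filtered segment. The amplitude correlation of epoch i pairs it with
#' epoch i+1; the final epoch copies the previous value and is flagged in
#' the `amp_corr_copied` column.
#'
#' @param segment an `eeg_segment` (already bandpass filtered) from
#'   [segment_signal()], or a numeric vector with `sampling_rate` given.
#' @param epoch_length seconds (default 0.5).
#' @param criteria a [spike_criteria()].
#' @param sampling_rate required for bare numeric input.
#' @param offset start time (s) of the segment within its recording; taken
#'   from the segment object when available.
#' @param band_lower,band_upper band edges for [band_power_ratio()].
#' @param band_mode `"ratio"` or `"difference"`.
#' @return data.frame with one row per epoch: `epoch_start` (s, relative to
#'   recording start), `amp_corr`, `rms`, `spike_density`, `band_ratio`,
#'   `amp_corr_copied`.
#' @export
feature_matrix <- function(segment, epoch_length = 0.5,
                           criteria = spike_criteria(),
                           sampling_rate = NULL, offset = NULL,
                           band_lower = c(0.5, 20), band_upper = c(20, 50),
                           band_mode = "ratio") {
  if (inherits(segment, "eeg_segment")) {
    x <- segment$samples
    fs <- segment$sampling_rate
    if (is.null(offset)) offset <- segment$offset
  } else {
    x <- segment
    stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
    fs <- sampling_rate
    if (is.null(offset)) offset <- 0
  }
  ep <- epoch_matrix(x, fs, epoch_length)
  k <- ncol(ep)
  if (k == 0)
    return(data.frame(epoch_start = numeric(0), amp_corr = numeric(0),
                      rms = numeric(0), spike_density = numeric(0),
                      band_ratio = numeric(0), amp_corr_copied = logical(0)))
  n_ep <- nrow(ep)

  rms <- sqrt(colMeans(ep^2))

  # lag-0 Pearson correlation of consecutive epoch columns, vectorised
  ctr <- ep - matrix(colMeans(ep), n_ep, k, byrow = TRUE)
  ss <- colSums(ctr^2)
  amp_corr <- rep(0, k)
  copied <- rep(FALSE, k)
  if (k >= 2) {
    num <- colSums(ctr[, -k, drop = FALSE] * ctr[, -1L, drop = FALSE])
    den <- sqrt(ss[-k] * ss[-1L])
    ac <- ifelse(den == 0, 0, num / den)
    amp_corr[seq_len(k - 1L)] <- ac
    amp_corr[k] <- ac[k - 1L]
    copied[k] <- TRUE
  } else {
    copied[1L] <- TRUE
  }

  scale <- robust_segment_scale(x)
  spikes <- vapply(seq_len(k), function(i)
    spike_density(ep[, i], fs, scale, criteria), numeric(1))

  # Hann-windowed periodogram of all epochs at once
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n_ep) - 1) / n_ep))
  p <- Mod(stats::mvfft(ep * w))^2
  nf <- floor(n_ep / 2)
  freqs <- seq_len(nf) * fs / n_ep
  p <- p[2:(nf + 1L), , drop = FALSE]
  lo <- colSums(p[freqs >= band_lower[1] & freqs < band_lower[2], , drop = FALSE])
  hi <- colSums(p[freqs >= band_upper[1] & freqs < band_upper[2], , drop = FALSE])
  band <- if (identical(band_mode, "difference")) {
    tot <- colSums(p)
    ifelse(tot == 0, 0, (hi - lo) / tot)
  } else {
    hi / (lo + 1e-12 * colSums(p))
  }

  data.frame(epoch_start = offset + (seq_len(k) - 1L) * epoch_length,
             amp_corr = amp_corr, rms = rms, spike_density = spikes,
             band_ratio = band, amp_corr_copied = copied)
}
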