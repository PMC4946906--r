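#' Multi-channel EEG recording
#'
#' Container for a uniformly sampled multi-channel EEG signal in microvolts.
#' Samples are stored as a channels x time numeric matrix.
#'
#' @param samples numeric matrix (channels x samples) or vector (one
#'   channel), in microvolts.
#' @param sampling_rate sampling rate in Hz.
#' @param channel_labels character vector of channel names; defaults to
#'   `"ch1"`, `"ch2"`, ...
#' @param start_time recording start offset in seconds (default 0).
#' @return An object of class `eeg_recording`: a list with elements
#'   `samples`, `sampling_rate`, `channel_labels`, `start_time`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(4000), nrow = 2), 2000)
#' rec_duration(rec)
#' @export
eeg_recording <- function(samples, sampling_rate, channel_labels = NULL,
                          start_time = 0) {
  if (is.vector(samples) && is.numeric(samples))
    samples <- matrix(samples, nrow = 1L)
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("'samples' must be a numeric matrix (channels x samples)",
         call. = FALSE)
  if (!all(is.finite(samples)))
    stop("'samples' must contain only finite values", call. = FALSE)
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(nrow(samples)))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(samples))
    stop("one channel label per row of 'samples' is required", call. = FALSE)
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique", call. = FALSE)
  structure(
    list(samples = samples,
         sampling_rate = sampling_rate,
         channel_labels = channel_labels,
         start_time = start_time),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s), %.1f s at %g Hz\n",
              nrow(x$samples), rec_duration(x), x$sampling_rate))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Recording duration in seconds
#'
#' @param recording an [eeg_recording()].
#' @return duration in seconds (`n_samples / sampling_rate`).
#' @export
rec_duration <- function(recording) {
  ncol(recording$samples) / recording$sampling_rate
}

#' Event annotation table
#'
#' Labelled time intervals on named channels, used both for injected
#' ground-truth events and for detector output. Times are seconds from
#' recording start; intervals are half-open `[start, end)`.
#'
#' @param channel character vector of channel labels.
#' @param start,end numeric vectors of interval bounds in seconds.
#' @param label character vector of event labels (recycled).
#' @return A `data.frame` with columns `channel`, `start`, `end`, `label`,
#'   sorted by (channel, start).
#' @examples
#' event_table("ch1", start = c(10, 3), end = c(14, 7), label = "swd")
#' @export
event_table <- function(channel = character(), start = numeric(),
                        end = numeric(), label = character()) {
  n <- length(start)
  if (length(end) != n)
    stop("'start' and 'end' must have equal length", call. = FALSE)
  if (n > 0 && any(end <= start))
    stop(sprintf("event end must exceed start (first bad row: %d)",
                 which(end <= start)[1L]), call. = FALSE)
  if (n > 0 && any(start < 0))
    stop("event start times must be >= 0", call. = FALSE)
  df <- data.frame(channel = as.character(rep_len(if (n) channel else character(), n)),
                   start = as.numeric(start), end = as.numeric(end),
                   label = as.character(rep_len(if (n) label else character(), n)),
                   stringsAsFactors = FALSE)
  df[order(df$channel, df$start), , drop = FALSE]
}
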