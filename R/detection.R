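# Joint thresholding of the four epoch features, merging of flagged epochs
# into seizure candidates, episode statistics, and accuracy against ground
# truth.

#' Threshold specification for the four detection features
#'
#' Each feature is thresholded either on an absolute value or on a robust
#' z-scale computed from the recording itself (threshold = median + z x
#' 1.4826 x MAD over all epochs). Defaults: robust z = 3 for RMS, spike
#' density and band ratio; absolute 0.5 for the amplitude correlation
#' (rhythmic discharges correlate consecutive epochs strongly, and the
#' correlation is already on a fixed \[-1, 1\] scale).
#'
#' @param amp_corr,rms,spike_density,band_ratio each a list with elements
#'   `mode` (`"absolute"` or `"robust_z"`) and `value` (absolute threshold
#'   or z multiplier).
#' @return list of class `threshold_spec`.
#' @export
threshold_spec <- function(amp_corr = list(mode = "absolute", value = 0.5),
                           rms = list(mode = "robust_z", value = 3),
                           spike_density = list(mode = "robust_z", value = 3),
                           band_ratio = list(mode = "robust_z", value = 3)) {
  spec <- list(amp_corr = amp_corr, rms = rms,
               spike_density = spike_density, band_ratio = band_ratio)
  for (nm in names(spec)) {
    s <- spec[[nm]]
    if (!is.list(s) || !all(c("mode", "value") %in% names(s)) ||
        !s$mode %in% c("absolute", "robust_z"))
      stop(sprintf("'%s' must be list(mode = 'absolute'|'robust_z', value =)",
                   nm), call. = FALSE)
  }
  structure(spec, class = "threshold_spec")
}

#' Detection configuration
#'
#' Gathers every constant of the detection algorithm: segmentation length,
#' bandpass specification, epoch length, spike criteria, feature options,
#' thresholds, and merge rules.
#'
#' @param filter a [filter_spec()].
#' @param segment_length seconds (default 600: 10-minute segments).
#' @param epoch_length seconds (default 0.5).
#' @param spike a [spike_criteria()].
#' @param thresholds a [threshold_spec()].
#' @param max_gap_epochs unflagged epochs bridged when merging (default 1).
#' @param min_duration minimum candidate duration in seconds (default 1).
#' @param band_lower,band_upper band edges in Hz for the power ratio.
#' @param band_mode `"ratio"` or `"difference"`.
#' @return list of class `detection_config`.
#' @export
detection_config <- function(filter = filter_spec(), segment_length = 600,
                             epoch_length = 0.5, spike = spike_criteria(),
                             thresholds = threshold_spec(),
                             max_gap_epochs = 1, min_duration = 1,
                             band_lower = c(0.5, 20), band_upper = c(20, 50),
                             band_mode = "ratio") {
  stopifnot(inherits(filter, "filter_spec"),
            inherits(spike, "spike_criteria"),
            inherits(thresholds, "threshold_spec"))
  stopifnot_scalar(segment_length, "segment_length", positive = TRUE)
  stopifnot_scalar(epoch_length, "epoch_length", positive = TRUE)
  stopifnot_scalar(max_gap_epochs, "max_gap_epochs", nonneg = TRUE)
  stopifnot_scalar(min_duration, "min_duration", nonneg = TRUE)
  structure(list(filter = filter, segment_length = segment_length,
                 epoch_length = epoch_length, spike = spike,
                 thresholds = thresholds,
                 max_gap_epochs = as.integer(max_gap_epochs),
                 min_duration = min_duration,
                 band_lower = band_lower, band_upper = band_upper,
                 band_mode = band_mode),
            class = "detection_config")
}

#' Compute per-feature thresholds from a feature table
#'
#' Robust-z thresholds are `median + z x 1.4826 x MAD` over all epochs of
#' the recording (MAD floored at `1e-9 x |median|` so a degenerate
#' feature column still yields a usable threshold); absolute thresholds
#' pass through. Robust mode requires at least 100 epochs.
#'
#' @param table an epoch feature table (from [feature_matrix()], possibly
#'   row-bound over segments and channels).
#' @param spec a [threshold_spec()].
#' @return named numeric vector of thresholds for `amp_corr`, `rms`,
#'   `spike_density`, `band_ratio`.
#' @export
compute_thresholds <- function(table, spec = threshold_spec()) {
  stopifnot(inherits(spec, "threshold_spec"))
  needs_z <- vapply(spec, function(s) s$mode == "robust_z", logical(1))
  if (any(needs_z) && nrow(table) < 100)
    stop("robust_z thresholds need >= 100 epochs; use absolute mode for ",
         "short recordings", call. = FALSE)
  vapply(names(spec), function(nm) {
    s <- spec[[nm]]
    if (s$mode == "absolute") return(s$value)
    x <- table[[nm]]
    stats::median(x) + s$value * robust_scale(x)
  }, numeric(1))
}

#' Flag epochs exceeding every feature threshold
#'
#' An epoch is a candidate epoch iff all four features strictly exceed
#' their thresholds (logical AND).
#'
#' @param table epoch feature table.
#' @param thresholds named vector from [compute_thresholds()].
#' @return logical vector, one element per epoch.
#' @export
flag_epochs <- function(table, thresholds) {
  need <- c("amp_corr", "rms", "spike_density", "band_ratio")
  if (!all(need %in% names(thresholds)))
    stop("thresholds must name all four features", call. = FALSE)
  table$amp_corr > thresholds[["amp_corr"]] &
    table$rms > thresholds[["rms"]] &
    table$spike_density > thresholds[["spike_density"]] &
    table$band_ratio > thresholds[["band_ratio"]]
}

#' Merge flagged epochs into seizure candidates
#'
#' Maximal runs of flagged epochs become candidate intervals; interior
#' gaps of at most `max_gap_epochs` unflagged epochs are bridged; merged
#' runs shorter than `min_duration` seconds are discarded.
#'
#' @param flags logical vector aligned to the epoch grid.
#' @param epoch_length seconds per epoch.
#' @param max_gap_epochs gap-bridging limit (default 1).
#' @param min_duration minimum candidate duration, s (default 1).
#' @param epoch_starts optional epoch start times (s); defaults to a grid
#'   starting at 0.
#' @return data.frame with columns `start`, `end`, `duration`, `n_epochs`
#'   (flagged epochs in the run), `first_epoch`, `last_epoch` (1-based
#'   indices).
#' @export
merge_candidates <- function(flags, epoch_length = 0.5, max_gap_epochs = 1,
                             min_duration = 1, epoch_starts = NULL) {
  if (is.null(epoch_starts))
    epoch_starts <- (seq_along(flags) - 1) * epoch_length
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0), n_epochs = integer(0),
                      first_epoch = integer(0), last_epoch = integer(0))
  idx <- which(flags)
  if (length(idx) == 0) return(empty)
  # successive flagged epochs belong to one run when separated by at most
  # max_gap_epochs unflagged epochs
  new_run <- c(TRUE, diff(idx) > max_gap_epochs + 1L)
  run_id <- cumsum(new_run)
  out <- do.call(rbind, lapply(split(idx, run_id), function(ii) {
    data.frame(start = epoch_starts[ii[1L]],
               end = epoch_starts[ii[length(ii)]] + epoch_length,
               duration = NA_real_, n_epochs = length(ii),
               first_epoch = ii[1L], last_epoch = ii[length(ii)])
  }))
  out$duration <- out$end - out$start
  out <- out[out$duration >= min_duration, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect spike-and-wave seizure candidates in a recording
#'
#' The full pipeline: each channel is split into 10-minute segments,
#' bandpass filtered (third-order Butterworth, 0.5-400 Hz, zero-phase),
#' cut into 500 ms epochs, and scored on the four features. Thresholds are
#' computed once over all epochs of the recording (all channels pooled),
#' epochs exceeding all four are flagged per channel, and flagged runs are
#' merged into candidates. The paper-trail of per-epoch features is kept
#' on the returned object for audit.
#'
#' @param recording an [eeg_recording()].
#' @param config a [detection_config()].
#' @return An object of class `swd_detection`: list with
#'   \describe{
#'     \item{candidates}{data.frame: `channel`, `start`, `end`, `duration`,
#'       `n_epochs`, and peak feature values per candidate
#'       (`peak_amp_corr`, `peak_rms`, `peak_spike_density`,
#'       `peak_band_ratio`), sorted by channel then start.}
#'     \item{features}{per-epoch feature table with `channel` column.}
#'     \item{thresholds}{named vector actually applied.}
#'     \item{config}{the configuration.}
#'     \item{recorded_hours}{recording length in hours.}
#'   }
#' @examples
#' \donttest{
#' sim <- simulate_eeg(sim_config(duration = 1200, seed = 3), n_events = 2)
#' det <- detect_swd(sim$recording)
#' det$candidates
#' }
#' @export
detect_swd <- function(recording, config = detection_config()) {
  stopifnot(inherits(recording, "eeg_recording"),
            inherits(config, "detection_config"))
  feats <- vector("list", length(recording$channel_labels))
  for (ci in seq_along(recording$channel_labels)) {
    segs <- segment_signal(recording, channel = ci,
                           segment_length = config$segment_length,
                           min_length = config$epoch_length)
    tabs <- lapply(segs, function(sg) {
      sg <- bandpass(sg, config$filter)
      feature_matrix(sg, epoch_length = config$epoch_length,
                     criteria = config$spike,
                     band_lower = config$band_lower,
                     band_upper = config$band_upper,
                     band_mode = config$band_mode)
    })
    tab <- do.call(rbind, tabs)
    tab$channel <- recording$channel_labels[ci]
    feats[[ci]] <- tab
  }
  features <- do.call(rbind, feats)
  thresholds <- compute_thresholds(features, config$thresholds)

  cands <- lapply(seq_along(recording$channel_labels), function(ci) {
    tab <- feats[[ci]]
    flags <- flag_epochs(tab, thresholds)
    cc <- merge_candidates(flags, epoch_length = config$epoch_length,
                           max_gap_epochs = config$max_gap_epochs,
                           min_duration = config$min_duration,
                           epoch_starts = tab$epoch_start)
    if (nrow(cc) == 0) return(NULL)
    peaks <- t(vapply(seq_len(nrow(cc)), function(i) {
      rows <- cc$first_epoch[i]:cc$last_epoch[i]
      c(max(tab$amp_corr[rows]), max(tab$rms[rows]),
        max(tab$spike_density[rows]), max(tab$band_ratio[rows]))
    }, numeric(4)))
    data.frame(channel = recording$channel_labels[ci],
               start = cc$start, end = cc$end, duration = cc$duration,
               n_epochs = cc$n_epochs,
               peak_amp_corr = peaks[, 1], peak_rms = peaks[, 2],
               peak_spike_density = peaks[, 3], peak_band_ratio = peaks[, 4],
               stringsAsFactors = FALSE)
  })
  candidates <- do.call(rbind, cands)
  if (is.null(candidates))
    candidates <- data.frame(channel = character(), start = numeric(),
                             end = numeric(), duration = numeric(),
                             n_epochs = integer(), peak_amp_corr = numeric(),
                             peak_rms = numeric(),
                             peak_spike_density = numeric(),
                             peak_band_ratio = numeric(),
                             stringsAsFactors = FALSE)
  candidates <- candidates[order(candidates$channel, candidates$start), ,
                           drop = FALSE]
  rownames(candidates) <- NULL
  structure(list(candidates = candidates, features = features,
                 thresholds = thresholds, config = config,
                 recorded_hours = rec_duration(recording) / 3600),
            class = "swd_detection")
}

#' Episode statistics of detected candidates
#'
#' Episodes per hour and mean +/- SEM of episode duration, per channel and
#' pooled across channels.
#'
#' @param candidates candidate data.frame (or an `swd_detection` object).
#' @param recorded_hours hours of recording the candidates came from; read
#'   off the detection object when one is given.
#' @return data.frame with rows per channel plus `"pooled"`: `channel`,
#'   `n_events`, `episodes_per_hour`, `mean_duration`, `sem_duration`
#'   (`NA` when fewer than 2 events).
#' @examples
#' ep <- data.frame(channel = "ch1", start = 0, end = 4, duration = c(3.5, 4, 4.5))
#' episode_statistics(ep, recorded_hours = 3)
#' @export
episode_statistics <- function(candidates, recorded_hours = NULL) {
  if (inherits(candidates, "swd_detection")) {
    if (is.null(recorded_hours)) recorded_hours <- candidates$recorded_hours
    candidates <- candidates$candidates
  }
  if (is.null(recorded_hours) || !is.numeric(recorded_hours) ||
      recorded_hours <= 0)
    stop("'recorded_hours' must be > 0", call. = FALSE)
  one <- function(dur, label) {
    n <- length(dur)
    data.frame(channel = label, n_events = n,
               episodes_per_hour = n / recorded_hours,
               mean_duration = if (n) mean(dur) else NA_real_,
               sem_duration = if (n >= 2) stats::sd(dur) / sqrt(n) else NA_real_,
               stringsAsFactors = FALSE)
  }
  chans <- unique(candidates$channel)
  per <- do.call(rbind, lapply(chans, function(ch)
    one(candidates$duration[candidates$channel == ch], ch)))
  pooled <- one(candidates$duration, "pooled")
  rbind(per, pooled)
}

#' Score candidates against ground-truth events
#'
#' One-to-one matching between candidates and truth intervals on the same
#' channel: a candidate may match a truth event when the candidate's
#' midpoint lies within `match_tolerance` seconds of the truth interval;
#' the maximum one-to-one matching under that rule is used (augmenting-path
#' bipartite matching, candidates in start order).
#'
#' @param candidates candidate data.frame with `channel`, `start`, `end`
#'   (an `swd_detection` object is also accepted).
#' @param truth an [event_table()] of true events.
#' @param match_tolerance seconds (default 2).
#' @return list of class `swd_accuracy`: `sensitivity`,
#'   `false_discovery_rate` (`NA` when there are no candidates),
#'   `mean_onset_error`, `mean_duration_error` (seconds, over matched
#'   pairs), `n_matched`, `n_truth`, `n_candidates`.
#' @export
evaluate_detection <- function(candidates, truth, match_tolerance = 2) {
  if (inherits(candidates, "swd_detection"))
    candidates <- candidates$candidates
  n_t <- nrow(truth); n_c <- nrow(candidates)
  # admissibility: candidate midpoint within tolerance of the truth interval,
  # same channel
  mid <- (candidates$start + candidates$end) / 2
  adm <- matrix(FALSE, n_c, n_t)
  if (n_c && n_t)
    for (i in seq_len(n_c)) {
      d <- pmax(truth$start - mid[i], mid[i] - truth$end, 0)
      adm[i, ] <- candidates$channel[i] == truth$channel & d <= match_tolerance
    }
  # maximum bipartite matching by augmenting paths
  match_t <- rep(0L, n_t)  # truth j -> candidate i
  augment <- function(i, seen) {
    for (j in which(adm[i, ])) {
      if (seen[j]) next
      seen[j] <- TRUE
      if (match_t[j] == 0L || Recall(match_t[j], seen)) {
        match_t[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  if (n_c && n_t)
    for (i in order(candidates$start)) augment(i, rep(FALSE, n_t))
  matched_j <- which(match_t > 0L)
  n_m <- length(matched_j)
  onset_err <- dur_err <- NA_real_
  if (n_m) {
    ci <- match_t[matched_j]
    onset_err <- mean(abs(candidates$start[ci] - truth$start[matched_j]))
    dur_err <- mean(abs((candidates$end[ci] - candidates$start[ci]) -
                        (truth$end[matched_j] - truth$start[matched_j])))
  }
  structure(list(
    sensitivity = if (n_t) n_m / n_t else NA_real_,
    false_discovery_rate = if (n_c) (n_c - n_m) / n_c else NA_real_,
    mean_onset_error = onset_err,
    mean_duration_error = dur_err,
    n_matched = n_m, n_truth = n_t, n_candidates = n_c),
    class = "swd_accuracy")
}

#' @export
print.swd_accuracy <- function(x, ...) {
  cat(sprintf(
    "<swd_accuracy> sensitivity %.3f, FDR %s (%d/%d truth matched, %d candidates)\n",
    x$sensitivity,
    if (is.na(x$false_discovery_rate)) "NA"
    else sprintf("%.3f", x$false_discovery_rate),
    x$n_matched, x$n_truth, x$n_candidates))
  if (!is.na(x$mean_onset_error))
    cat(sprintf("  mean |onset error| %.3f s, mean |duration error| %.3f s\n",
                x$mean_onset_error, x$mean_duration_error))
  invisible(x)
}
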