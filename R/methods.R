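# S3 methods for swd_detection objects.

#' @export
print.swd_detection <- function(x, ...) {
  cat(sprintf("<swd_detection> %d candidate(s) in %.2f h of EEG\n",
              nrow(x$candidates), x$recorded_hours))
  cat("  thresholds:",
      paste(sprintf("%s > %.4g", names(x$thresholds), x$thresholds),
            collapse = ", "), "\n")
  if (nrow(x$candidates)) {
    cat("  candidates:\n")
    print(utils::head(x$candidates[, c("channel", "start", "end",
                                       "duration", "n_epochs")], 10))
    if (nrow(x$candidates) > 10) cat("  ...\n")
  }
  invisible(x)
}

#' Summarise a detection: episode statistics per channel and pooled
#'
#' @param object an `swd_detection` from [detect_swd()].
#' @param ... unused.
#' @return the [episode_statistics()] data.frame, invisibly printed.
#' @export
summary.swd_detection <- function(object, ...) {
  stats <- episode_statistics(object)
  cat(sprintf("Seizure-candidate summary over %.2f h\n",
              object$recorded_hours))
  print(stats, row.names = FALSE)
  invisible(stats)
}

#' Thresholds applied by a detection
#'
#' @param object an `swd_detection`.
#' @param ... unused.
#' @return named numeric vector of the four feature thresholds.
#' @export
coef.swd_detection <- function(object, ...) object$thresholds

#' Plot per-epoch features with candidate intervals shaded
#'
#' Four stacked panels (amplitude correlation, RMS, spike density, band
#' ratio) against epoch start time, with the applied threshold as a dashed
#' line and detected candidate intervals shaded.
#'
#' @param x an `swd_detection`.
#' @param channel channel label to plot (default first).
#' @param xlim optional time range in seconds.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.swd_detection <- function(x, channel = NULL, xlim = NULL, ...) {
  if (is.null(channel)) channel <- x$features$channel[1L]
  tab <- x$features[x$features$channel == channel, , drop = FALSE]
  cand <- x$candidates[x$candidates$channel == channel, , drop = FALSE]
  feats <- c("amp_corr", "rms", "spike_density", "band_ratio")
  labs <- c("amplitude correlation", "RMS (uV)", "spikes / s",
            "band-power ratio")
  op <- graphics::par(mfrow = c(4, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  for (k in seq_along(feats)) {
    graphics::plot(tab$epoch_start, tab[[feats[k]]], type = "l",
                   xlab = "", ylab = labs[k], xlim = xlim, ...)
    graphics::abline(h = x$thresholds[[feats[k]]], lty = 2, col = "red")
    if (nrow(cand))
      graphics::rect(cand$start, graphics::par("usr")[3], cand$end,
                     graphics::par("usr")[4],
                     col = grDevices::adjustcolor("orange", 0.3), border = NA)
  }
  invisible(x)
}
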