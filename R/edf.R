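# Minimal 16-bit EDF (European Data Format) reader/writer: fixed-layout
# ASCII header, per-signal header block, then interleaved data records of
# 2-byte little-endian integers. One sampling rate across channels.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  for (d in 10:1) {
    s <- sprintf("%.*g", d, x)
    if (nchar(s) <= width) break
  }
  edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' 16-bit EDF with a 1-second data-record duration; every channel shares
#' the recording's sampling rate, which must be a whole number of samples
#' per second. The physical range is set per channel to cover the observed
#' minimum/maximum symmetrically, so quantisation error is bounded by the
#' physical range divided by 2^16. A recording whose length is not a whole
#' number of seconds is truncated to full records with a warning.
#'
#' @param recording an [eeg_recording()] (samples in uV).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  x <- recording$samples
  if (!all(is.finite(x)))
    stop("samples must be finite to write EDF", call. = FALSE)
  fs <- recording$sampling_rate
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  fs <- as.integer(round(fs))
  ns <- nrow(x)
  n_rec <- floor(ncol(x) / fs)
  if (n_rec < 1)
    stop("recording shorter than one 1-s data record", call. = FALSE)
  if (n_rec * fs < ncol(x)) {
    warning(sprintf("truncating %d trailing samples to full 1-s records",
                    ncol(x) - n_rec * fs))
    x <- x[, seq_len(n_rec * fs), drop = FALSE]
  }
  pmaxs <- apply(abs(x), 1, max)
  pmaxs[pmaxs == 0] <- 1
  # symmetric digital range so that 0 uV maps exactly to code 0; the
  # physical-min string is the negation of the physical-max string so the
  # header stores an exactly symmetric range despite ASCII rounding
  dmin <- -32767L; dmax <- 32767L
  pm_str <- vapply(pmaxs, function(p) trimws(edf_num(p, 7)), "")

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X", 80), edf_pad("swdkit", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4))
  sig <- paste0(
    paste(vapply(recording$channel_labels, edf_pad, "", width = 16),
          collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(vapply(pm_str, function(s) edf_pad(paste0("-", s), 8), ""),
          collapse = ""),
    paste(vapply(pm_str, edf_pad, "", width = 8), collapse = ""),
    paste(rep(edf_pad(dmin, 8), ns), collapse = ""),
    paste(rep(edf_pad(dmax, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(fs, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = ""))
  writeChar(paste0(hdr, sig), con, eos = NULL, useBytes = TRUE)

  # digitise per channel against the header's (string-rounded) range
  pm <- as.numeric(pm_str)
  dig <- matrix(0L, nrow = ns, ncol = ncol(x))
  for (ch in seq_len(ns)) {
    d <- round((x[ch, ] + pm[ch]) / (2 * pm[ch]) * (dmax - dmin) + dmin)
    dig[ch, ] <- as.integer(pmin(pmax(d, dmin), dmax))
  }
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

edf_field <- function(raw, off, len, name, numeric = FALSE) {
  s <- trimws(rawToChar(raw[(off + 1):(off + len)]))
  if (numeric) {
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v))
      stop(sprintf("malformed EDF header field '%s': '%s'", name, s),
           call. = FALSE)
    return(v)
  }
  s
}

#' Read an EDF file into a recording
#'
#' Supports the plain 16-bit EDF layout written by [write_edf()] and by
#' common acquisition systems: one sampling rate across channels. Samples
#' are converted to microvolts using each signal's physical dimension
#' field (`uV`, `mV` or `V`).
#'
#' @param path EDF file path.
#' @return an [eeg_recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  fixed <- readBin(con, "raw", 256)
  if (length(fixed) < 256)
    stop("malformed EDF: truncated fixed header", call. = FALSE)
  n_rec <- edf_field(fixed, 236, 8, "number of data records", numeric = TRUE)
  rec_dur <- edf_field(fixed, 244, 8, "duration of a data record",
                       numeric = TRUE)
  ns <- edf_field(fixed, 252, 4, "number of signals", numeric = TRUE)
  if (ns < 1 || ns != round(ns))
    stop("malformed EDF header field 'number of signals'", call. = FALSE)
  ns <- as.integer(ns)
  sig <- readBin(con, "raw", 256 * ns)
  if (length(sig) < 256 * ns)
    stop("malformed EDF: truncated signal header", call. = FALSE)
  # per-field block widths in bytes: label 16, transducer 80, dim 8,
  # pmin 8, pmax 8, dmin 8, dmax 8, prefilter 80, samples-per-record 8;
  # each block holds the field for all ns signals consecutively
  fld <- function(block_start, len, name)
    vapply(seq_len(ns), function(i)
      edf_field(sig, block_start + (i - 1L) * len, len,
                sprintf("%s[%d]", name, i)),
      character(1))
  nfld <- function(block_start, len, name)
    vapply(seq_len(ns), function(i)
      edf_field(sig, block_start + (i - 1L) * len, len,
                sprintf("%s[%d]", name, i), numeric = TRUE),
      numeric(1))
  labels <- fld(0, 16, "label")
  dims <- fld((16 + 80) * ns, 8, "physical dimension")
  pmin <- nfld((16 + 80 + 8) * ns, 8, "physical minimum")
  pmax <- nfld((16 + 80 + 16) * ns, 8, "physical maximum")
  dmin <- nfld((16 + 80 + 24) * ns, 8, "digital minimum")
  dmax <- nfld((16 + 80 + 32) * ns, 8, "digital maximum")
  spr  <- nfld((16 + 80 + 40 + 80) * ns, 8, "samples per record")
  if (length(unique(spr)) != 1)
    stop("unsupported EDF layout: channels with mixed sampling rates",
         call. = FALSE)
  if (any(pmax <= pmin) || any(dmax <= dmin))
    stop("malformed EDF header field 'physical/digital range'",
         call. = FALSE)
  spr <- as.integer(spr[1])
  fs <- spr / rec_dur
  unit_scale <- vapply(tolower(dims), function(d)
    switch(d, "uv" = 1, "µv" = 1, "mv" = 1e3, "v" = 1e6,
           { warning(sprintf("unknown physical dimension '%s'; assuming uV", d))
             1 }),
    numeric(1))
  n_samp <- n_rec * spr
  samples <- matrix(0, nrow = ns, ncol = n_samp)
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = spr * ns, size = 2, signed = TRUE,
                     endian = "little")
    if (length(block) < spr * ns)
      stop("malformed EDF: truncated data records", call. = FALSE)
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    samples[, cols] <- t(matrix(block, nrow = spr))
  }
  for (ch in seq_len(ns)) {
    samples[ch, ] <- ((samples[ch, ] - dmin[ch]) / (dmax[ch] - dmin[ch]) *
                        (pmax[ch] - pmin[ch]) + pmin[ch]) * unit_scale[ch]
  }
  eeg_recording(samples, fs, labels)
}
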