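# Shared fixture builders. All randomness is locally seeded so tests are
# order-independent.

# a short recording with known injected events, at full 2 kHz
small_sim <- function(duration = 120, seed = 42, n_events = 1,
                      n_channels = 1) {
  simulate_eeg(sim_config(duration = duration, n_channels = n_channels,
                          seed = seed),
               n_events = n_events)
}

# pure sinusoid epoch, amplitude A, frequency f, integer cycles over 0.5 s
sine_epoch <- function(f, A = 1, fs = 2000, len = 0.5, phase = 0) {
  A * sin(2 * pi * f * (seq_len(round(fs * len)) - 1) / fs + phase)
}

# brute-force run merger: reference implementation for merge_candidates
oracle_merge <- function(flags, epoch_length, max_gap, min_duration) {
  n <- length(flags)
  # bridge: any FALSE-run of length <= max_gap with TRUE on both sides
  bridged <- flags
  r <- rle(flags)
  pos <- cumsum(c(1, r$lengths))
  for (k in seq_along(r$values)) {
    if (!r$values[k] && k > 1 && k < length(r$values) &&
        r$lengths[k] <= max_gap)
      bridged[pos[k]:(pos[k + 1] - 1)] <- TRUE
  }
  r2 <- rle(bridged)
  pos2 <- cumsum(c(1, r2$lengths))
  out <- data.frame(start = numeric(0), end = numeric(0))
  for (k in seq_along(r2$values)) {
    if (!r2$values[k]) next
    s <- (pos2[k] - 1) * epoch_length
    e <- (pos2[k + 1] - 1) * epoch_length
    if (e - s >= min_duration) out <- rbind(out, data.frame(start = s, end = e))
  }
  out
}

# exhaustive maximum one-to-one matching between candidates and truth under
# the midpoint-within-tolerance rule; returns the number of matched truths
oracle_max_matching <- function(cand, truth, tol) {
  n_c <- nrow(cand); n_t <- nrow(truth)
  if (n_c == 0 || n_t == 0) return(0L)
  mid <- (cand$start + cand$end) / 2
  adm <- matrix(FALSE, n_c, n_t)
  for (i in seq_len(n_c)) {
    d <- pmax(truth$start - mid[i], mid[i] - truth$end, 0)
    adm[i, ] <- cand$channel[i] == truth$channel & d <= tol
  }
  best <- 0L
  rec <- function(j, used, matched) {
    if (j > n_t) { best <<- max(best, matched); return(invisible()) }
    # prune: even matching all remaining truths cannot beat best
    if (matched + (n_t - j + 1) <= best) return(invisible())
    rec(j + 1, used, matched)                     # truth j unmatched
    for (i in which(adm[, j]))
      if (!used[i]) { used[i] <- TRUE; rec(j + 1, used, matched + 1L)
                      used[i] <- FALSE }
  }
  rec(1L, rep(FALSE, n_c), 0L)
  best
}
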