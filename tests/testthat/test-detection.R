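# Thresholding, merging, end-to-end detection, statistics, accuracy.

make_table <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(epoch_start = (seq_len(n) - 1) * 0.5,
             amp_corr = runif(n, -1, 1), rms = rexp(n, 1 / 30),
             spike_density = rpois(n, 0.2) * 2, band_ratio = rexp(n, 2))
}

test_that("thresholds: absolute passthrough and robust-z arithmetic", {
  tab <- make_table(1000)
  spec <- threshold_spec(amp_corr = list(mode = "absolute", value = 7),
                         rms = list(mode = "absolute", value = 7),
                         spike_density = list(mode = "absolute", value = 7),
                         band_ratio = list(mode = "absolute", value = 7))
  expect_equal(unname(compute_thresholds(tab, spec)), rep(7, 4))

  # hand-computed robust-z threshold on a designed column
  tab$rms <- c(rep(1, 999), 100)   # median 1, MAD 0 -> floored scale
  thr <- compute_thresholds(tab)
  expect_equal(thr[["rms"]], 1, tolerance = 1e-6)

  # Gaussian column at z = 3: about 0.13% of epochs exceed
  frac <- vapply(1:10, function(s) {
    set.seed(s)
    tb <- make_table(20000, seed = s)
    tb$rms <- rnorm(20000)
    mean(tb$rms > compute_thresholds(tb)[["rms"]])
  }, numeric(1))
  expect_lt(abs(mean(frac) - 0.00135), 0.001)

  expect_error(compute_thresholds(make_table(50)), "100 epochs")
})

test_that("epoch flagging is a strict four-way conjunction", {
  thr <- c(amp_corr = 0.5, rms = 10, spike_density = 2, band_ratio = 1)
  tab <- data.frame(amp_corr = c(0.9, 0.9, 0.4, 0.5),
                    rms = c(20, 20, 20, 20),
                    spike_density = c(4, 1, 4, 4),
                    band_ratio = c(2, 2, 2, 2))
  expect_equal(flag_epochs(tab, thr), c(TRUE, FALSE, FALSE, FALSE))

  # brute-force re-evaluation on random tables
  for (s in 1:5) {
    tab <- make_table(500, seed = s)
    got <- flag_epochs(tab, thr)
    want <- vapply(seq_len(500), function(i)
      tab$amp_corr[i] > 0.5 && tab$rms[i] > 10 &&
        tab$spike_density[i] > 2 && tab$band_ratio[i] > 1, logical(1))
    expect_identical(got, want)
  }
})

test_that("merging bridges short gaps and enforces minimum duration", {
  got <- merge_candidates(c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(nrow(got), 1)
  expect_equal(got$end - got$start, 2.5)
  expect_equal(got$n_epochs, 4)  # flagged epochs only

  # two sub-minimum runs vanish
  expect_equal(nrow(merge_candidates(c(TRUE, FALSE, FALSE, TRUE))), 0)

  # random flag vectors match the brute-force oracle
  for (s in 1:100) {
    set.seed(s)
    flags <- runif(60) < 0.3
    gap <- sample(0:2, 1)
    md <- sample(c(0.5, 1, 1.5), 1)
    got <- merge_candidates(flags, max_gap_epochs = gap, min_duration = md)
    want <- oracle_merge(flags, 0.5, gap, md)
    expect_equal(got[, c("start", "end")], want,
                 ignore_attr = TRUE)
    if (nrow(got) > 1)
      expect_true(all(got$start[-1] >= got$end[-nrow(got)]))
  }
})

test_that("episode statistics follow the rate and SEM definitions", {
  cand <- data.frame(channel = "ch1", start = 0, end = 1,
                     duration = c(3.5, 4.0, 4.5))
  st <- episode_statistics(cand, recorded_hours = 3)
  pooled <- st[st$channel == "pooled", ]
  expect_equal(pooled$episodes_per_hour, 1.0)
  expect_equal(pooled$mean_duration, 4.0)
  expect_equal(pooled$sem_duration, 0.5 / sqrt(3), tolerance = 1e-4)

  st2 <- episode_statistics(data.frame(channel = "ch1", duration = rep(4, 3)),
                            recorded_hours = 3)
  expect_equal(st2$sem_duration[st2$channel == "pooled"], 0)

  # 10 events in 3 h -> 3.33/h; single event has undefined SEM
  st3 <- episode_statistics(data.frame(channel = "a", duration = rep(2, 10)),
                            recorded_hours = 3)
  expect_equal(st3$episodes_per_hour[st3$channel == "pooled"], 10 / 3)
  st4 <- episode_statistics(data.frame(channel = "a", duration = 2),
                            recorded_hours = 1)
  expect_true(is.na(st4$sem_duration[1]))

  expect_error(episode_statistics(cand, recorded_hours = 0), "> 0")
})

test_that("detection accuracy matches an exhaustive matching oracle", {
  # identity: perfect candidates
  truth <- event_table("ch1", c(10, 30), c(14, 34), "swd")
  acc <- evaluate_detection(truth, truth)
  expect_equal(acc$sensitivity, 1)
  expect_equal(acc$false_discovery_rate, 0)
  expect_equal(acc$mean_onset_error, 0)

  # empty candidates
  acc0 <- evaluate_detection(event_table(), truth)
  expect_equal(acc0$sensitivity, 0)
  expect_true(is.na(acc0$false_discovery_rate))

  # random small instances vs brute force
  for (s in 1:100) {
    set.seed(s)
    nt <- sample(0:6, 1); nc <- sample(0:6, 1)
    truth <- if (nt) {
      st <- sort(runif(nt, 0, 100))
      event_table(rep("ch1", nt), st, st + runif(nt, 1, 5), "swd")
    } else event_table()
    cand <- if (nc) {
      st <- sort(runif(nc, 0, 100))
      data.frame(channel = "ch1", start = st, end = st + runif(nc, 1, 5))
    } else data.frame(channel = character(), start = numeric(),
                      end = numeric())
    acc <- evaluate_detection(cand, truth, match_tolerance = 3)
    want <- oracle_max_matching(cand, truth, 3)
    expect_equal(acc$n_matched, want)
    if (nt) expect_equal(acc$sensitivity, want / nt)
    if (nc) expect_equal(acc$false_discovery_rate, (nc - want) / nc)
  }
})

test_that("detect_swd is deterministic, scale-invariant and recovers events", {
  sim <- small_sim(duration = 600, seed = 91, n_events = 2)
  det1 <- detect_swd(sim$recording)
  det2 <- detect_swd(sim$recording)
  expect_identical(det1$candidates, det2$candidates)

  # candidates sorted by start, midpoints inside the truth intervals
  expect_false(is.unsorted(det1$candidates$start))
  expect_gte(evaluate_detection(det1, sim$truth)$sensitivity, 0.5)

  # pure gain change leaves the candidate set identical (robust-z thresholds)
  rec2 <- sim$recording
  rec2$samples <- 2 * rec2$samples
  det3 <- detect_swd(rec2)
  expect_equal(det3$candidates[, c("channel", "start", "end", "n_epochs")],
               det1$candidates[, c("channel", "start", "end", "n_epochs")])

  # S3 surface
  expect_named(coef(det1),
               c("amp_corr", "rms", "spike_density", "band_ratio"))
  expect_output(print(det1), "swd_detection")
  st <- summary(det1)
  expect_true("pooled" %in% st$channel)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(det1))
})

test_that("raising any single threshold never increases flagged epochs", {
  tab <- make_table(2000, seed = 7)
  base <- c(amp_corr = 0.3, rms = 25, spike_density = 1, band_ratio = 0.8)
  n0 <- sum(flag_epochs(tab, base))
  set.seed(8)
  for (k in 1:50) {
    f <- sample(names(base), 1)
    thr <- base
    thr[f] <- thr[f] + runif(1, 0, 2) * abs(thr[f])
    expect_lte(sum(flag_epochs(tab, thr)), n0)
  }

  # AND-restrictiveness: conjunction flags no more than any single feature
  flags <- flag_epochs(tab, base)
  expect_lte(sum(flags), sum(tab$rms > base["rms"]))
  expect_lte(sum(flags), sum(tab$amp_corr > base["amp_corr"]))
})
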