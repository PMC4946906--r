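# The four per-epoch features and the feature table.

test_that("epoching is exact with trailing remainder dropped", {
  fs <- 2000
  m <- epoch_matrix(rnorm(600 * fs), fs)
  expect_equal(dim(m), c(1000, 1200))

  m2 <- epoch_matrix(rnorm(2400), fs)  # 1.2 s -> 2 epochs, 0.2 s dropped
  expect_equal(ncol(m2), 2)

  expect_warning(m3 <- epoch_matrix(rnorm(10), fs), "shorter")
  expect_equal(ncol(m3), 0)

  ft <- feature_matrix(rnorm(3 * fs), sampling_rate = fs)
  expect_equal(ft$epoch_start, c(0, 0.5, 1.0, 1.5, 2.0, 2.5))
})

test_that("amplitude correlation has the Pearson closed forms", {
  x <- rnorm(1000)
  expect_equal(amplitude_correlation(x, x), 1)
  expect_equal(amplitude_correlation(x, -x), -1)
  expect_error(amplitude_correlation(x, x[-1]), "equal length")

  z <- amplitude_correlation(rep(1, 100), rnorm(100))
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "degenerate"))

  # null distribution: independent white-noise epochs decorrelate
  set.seed(61)
  vals <- replicate(1000, abs(cor(rnorm(1000), rnorm(1000))))
  expect_gte(mean(vals < 0.1), 0.95)
})

test_that("rms matches closed forms and scales equivariantly", {
  expect_equal(epoch_rms(rep(-3, 100)), 3)
  expect_equal(epoch_rms(numeric(100)), 0)
  s <- sine_epoch(10, A = 7)  # integer cycles in 0.5 s
  expect_equal(epoch_rms(s), 7 / sqrt(2), tolerance = 1e-6)
  x <- rnorm(500)
  expect_equal(epoch_rms(-2.5 * x), 2.5 * epoch_rms(x))
})

test_that("spike density counts suprathreshold extrema with refractory", {
  fs <- 2000
  # 4 isolated biphasic-ish pulses of amplitude 10 in 0.5 s, scale 1
  x <- numeric(1000)
  for (c0 in c(100, 350, 600, 850)) {
    x[c0 + (-2:2)] <- 10 * c(0.2, 0.7, 1, 0.7, 0.2)
  }
  expect_equal(spike_density(x, fs, segment_scale = 1), 8)  # 4 / 0.5 s

  expect_equal(spike_density(numeric(1000), fs, segment_scale = 1), 0)

  # subthreshold sinusoid: amplitude half the 5-sigma threshold
  expect_equal(spike_density(sine_epoch(10, A = 2.5), fs, segment_scale = 1),
               0)

  # refractory: two extrema 10 ms apart count once, keeping the larger
  y <- numeric(1000)
  y[500 + (-1:1)] <- c(4, 8, 4)
  y[520 + (-1:1)] <- c(5, 10, 5)
  expect_equal(spike_density(y, fs, segment_scale = 1), 2)  # 1 spike / 0.5 s
  crit0 <- spike_criteria(refractory = 0)
  expect_equal(spike_density(y, fs, segment_scale = 1, criteria = crit0), 4)

  expect_error(spike_density(x, fs, segment_scale = 0), "positive")
})

test_that("band power ratio separates pure tones by band", {
  fs <- 2000
  expect_gt(band_power_ratio(sine_epoch(30), fs), 100)
  expect_lt(band_power_ratio(sine_epoch(10), fs), 0.01)
  two <- sine_epoch(10) + sine_epoch(30)
  r <- band_power_ratio(two, fs)
  expect_gt(r, 0.8); expect_lt(r, 1.25)

  # scale invariance
  x <- rnorm(1000)
  expect_equal(band_power_ratio(3 * x, fs), band_power_ratio(x, fs))

  # difference mode is bounded and sign-consistent
  expect_gt(band_power_ratio(sine_epoch(30), fs, mode = "difference"), 0.9)
  expect_lt(band_power_ratio(sine_epoch(10), fs, mode = "difference"), -0.9)
})

test_that("feature_matrix agrees with per-epoch recomputation", {
  fs <- 2000
  sim <- small_sim(duration = 12, seed = 71, n_events = 1)
  x <- bandpass(sim$recording$samples[1, ], sampling_rate = fs)
  ft <- feature_matrix(x, sampling_rate = fs)
  expect_equal(nrow(ft), 24)

  scale <- robust_segment_scale(x)
  ep <- epoch_matrix(x, fs)
  for (i in c(1, 5, 24)) {
    expect_equal(ft$rms[i], epoch_rms(ep[, i]))
    expect_equal(ft$spike_density[i], spike_density(ep[, i], fs, scale))
    expect_equal(ft$band_ratio[i], band_power_ratio(ep[, i], fs))
    if (i < 24)
      expect_equal(ft$amp_corr[i],
                   as.numeric(amplitude_correlation(ep[, i], ep[, i + 1])))
  }
  # last epoch copies the previous pair's value, flagged
  expect_equal(ft$amp_corr[24], ft$amp_corr[23])
  expect_true(ft$amp_corr_copied[24])
  expect_false(any(ft$amp_corr_copied[-24]))

  # determinism
  expect_identical(ft, feature_matrix(x, sampling_rate = fs))
})

test_that("injected SWD epochs separate from background on three features", {
  sim <- small_sim(duration = 120, seed = 81, n_events = 3)
  fs <- 2000
  x <- bandpass(sim$recording$samples[1, ], sampling_rate = fs)
  ft <- feature_matrix(x, sampling_rate = fs)
  inside <- rep(FALSE, nrow(ft))
  for (i in seq_len(nrow(sim$truth)))
    inside <- inside | (ft$epoch_start >= sim$truth$start[i] &
                          ft$epoch_start + 0.5 <= sim$truth$end[i])
  expect_gt(sum(inside), 10)
  for (f in c("rms", "spike_density", "band_ratio")) {
    expect_gt(median(ft[[f]][inside]), median(ft[[f]][!inside]))
  }
  expect_gt(median(ft$amp_corr[inside]), 0.5)
})
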