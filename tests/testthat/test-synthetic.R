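# Synthetic-EEG generator: background, event schedule, SWD waveform,
# injection.

test_that("background generation hits the target RMS and is deterministic", {
  cfg <- sim_config(duration = 120, seed = 42)
  bg1 <- generate_background(cfg)
  bg2 <- generate_background(cfg)
  expect_identical(bg1$samples, bg2$samples)
  expect_equal(ncol(bg1$samples), 120 * 2000)
  r <- sqrt(mean(bg1$samples^2))
  expect_gt(r, 45)
  expect_lt(r, 55)

  # zero-amplitude background is exactly zero
  cfg0 <- sim_config(duration = 2, seed = 1,
                     background = background_params(rms_amplitude = 0))
  expect_true(all(generate_background(cfg0)$samples == 0))
})

test_that("background spectral exponent shapes the spectrum", {
  # steeper exponent => relatively less high-frequency power
  r_of <- function(alpha) {
    cfg <- sim_config(duration = 30, seed = 3,
                      background = background_params(spectral_exponent = alpha))
    x <- generate_background(cfg)$samples[1, 1:1000]
    band_power_ratio(x, 2000)
  }
  expect_gt(r_of(0), r_of(1))
  expect_gt(r_of(1), r_of(2))
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(duration = -1), "duration")
  expect_error(background_params(rms_amplitude = -5), "rms_amplitude")
  expect_error(background_params(spectral_exponent = 5), "0, 3")
  expect_error(swd_params(rate = -1), "rate")
  expect_error(swd_params(fundamental = 25), "< 20")
  expect_error(swd_params(duration_mean = 1, duration_min = 2),
               "duration_mean")
  # sampling rate must clear the highest synthesised frequency
  expect_error(sim_config(duration = 10, sampling_rate = 60), "Nyquist|twice")
})

test_that("event schedules respect spacing, bounds and the Poisson rate", {
  swd <- swd_params()
  expect_equal(nrow(sample_event_schedule(swd_params(rate = 0), 3600,
                                          seed = 1)), 0)

  # brute-force pairwise non-overlap (with 1 s spacing) over many draws
  for (s in 1:20) {
    sch <- sample_event_schedule(swd_params(rate = 30), 3600, seed = s)
    if (nrow(sch) < 2) next
    expect_false(is.unsorted(sch$start))
    for (i in seq_len(nrow(sch) - 1)) for (j in (i + 1):nrow(sch)) {
      expect_true(sch$start[j] >= sch$start[i] + sch$duration[i] + 1 ||
                    sch$start[i] >= sch$start[j] + sch$duration[j] + 1)
    }
    expect_true(all(sch$start >= 0 &
                      sch$start + sch$duration <= 3600))
    expect_true(all(sch$duration >= swd$duration_min))
  }

  # Monte-Carlo mean of the Poisson count: 1000 x 2 h at 3.3/h => mean 6.6
  counts <- vapply(1:1000, function(s)
    nrow(sample_event_schedule(swd, 7200, seed = s)), numeric(1))
  se <- sqrt(6.6 / 1000)
  expect_lt(abs(mean(counts) - 6.6), 3 * se)
})

test_that("long-run schedule calibration matches rate and mean duration", {
  # 500 simulated hours: empirical rate within 5% of 3.3/h, mean duration
  # within 5% of 4.1 s
  swd <- swd_params()
  n_ev <- 0; tot_dur <- 0
  for (s in 1:250) {
    sch <- sample_event_schedule(swd, 7200, seed = 5000 + s)
    n_ev <- n_ev + nrow(sch)
    tot_dur <- tot_dur + sum(sch$duration)
  }
  expect_lt(abs(n_ev / 500 - 3.3), 0.05 * 3.3)
  expect_lt(abs(tot_dur / n_ev - 4.1), 0.05 * 4.1)
})

test_that("SWD waveform has the right length, peak frequency and band power", {
  swd <- swd_params()
  w <- synthesize_swd(4, swd, 2000, seed = 7)
  expect_length(w, 8000)
  expect_equal(sqrt(mean(w^2)), 1, tolerance = 1e-10)

  # dominant periodogram peak at the fundamental +/- 0.5 Hz
  p <- Mod(stats::fft(w))^2
  fr <- (seq_along(w) - 1) * 2000 / length(w)
  keep <- fr > 0.25 & fr <= 1000
  expect_lt(abs(fr[keep][which.max(p[keep])] - 6), 0.5)

  # more 20-50 Hz power than a pure fundamental sinusoid of equal RMS
  sine <- sqrt(2) * sin(2 * pi * 6 * (0:7999) / 2000)
  expect_gt(band_power_ratio(w[2001:3000], 2000),
            band_power_ratio(sine[2001:3000], 2000))

  # and than background of equal RMS
  bg <- generate_background(sim_config(duration = 4, seed = 8))
  x <- bg$samples[1, 1:1000] / sqrt(mean(bg$samples[1, 1:1000]^2))
  expect_gt(band_power_ratio(w[2001:3000], 2000),
            band_power_ratio(x, 2000))

  expect_error(synthesize_swd(0.1, swd, 2000), "one cycle")
})

test_that("injection touches only the scheduled intervals", {
  cfg <- sim_config(duration = 30, seed = 9)
  bg <- generate_background(cfg)

  # empty schedule: bit-identical
  empty <- data.frame(start = numeric(0), duration = numeric(0))
  out <- inject_events(bg, empty, cfg$swd)
  expect_identical(out$recording$samples, bg$samples)
  expect_equal(nrow(out$events), 0)

  # single event at 10-14 s: outside samples untouched
  sch <- data.frame(start = 10, duration = 4)
  out <- inject_events(bg, sch, cfg$swd, seed = 1)
  fs <- 2000
  expect_identical(out$recording$samples[, 1:(10 * fs)],
                   bg$samples[, 1:(10 * fs)])
  expect_identical(out$recording$samples[, (14 * fs + 2):(30 * fs)],
                   bg$samples[, (14 * fs + 2):(30 * fs)])
  expect_false(identical(out$recording$samples[, (10 * fs + 1):(14 * fs)],
                         bg$samples[, (10 * fs + 1):(14 * fs)]))

  # annotations mirror the schedule
  expect_equal(out$events$end - out$events$start, sch$duration)
  expect_equal(out$events$start, sch$start)
  expect_equal(out$events$label, "swd")

  # out-of-bounds event rejected
  expect_error(inject_events(bg, data.frame(start = 28, duration = 4),
                             cfg$swd), "beyond")
})

test_that("the full simulation is deterministic given the seed", {
  a <- small_sim(duration = 20, seed = 11, n_events = 1)
  b <- small_sim(duration = 20, seed = 11, n_events = 1)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$truth, b$truth)
  c <- small_sim(duration = 20, seed = 12, n_events = 1)
  expect_false(identical(a$recording$samples, c$recording$samples))
})
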