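# Spindle pipeline: despiking, 1024 Hz resampling, detrending, sigma
# bandpass, envelope detection against the NREM baseline, metrics and
# density, and end-to-end recovery of planted bursts.

test_that("despike excises transients and bridges them linearly", {
  set.seed(1)
  fs <- 1000
  x <- rnorm(10 * fs)
  expect_identical(as.numeric(despike(x, fs)), x)  # spike-free unchanged
  # single spike sample, no widening: replaced by the neighbor mean
  xs <- x; xs[5000] <- 9 * mad(x)
  y <- despike(xs, fs, pad_ms = 0)
  expect_equal(y[5000], (xs[4999] + xs[5001]) / 2)
  # default widening removes the whole 5-SD excursion
  xs2 <- x
  shape <- c(sin(pi * 1:3 / 4), -sin(pi * 1:3 / 4))
  xs2[6000:6005] <- xs2[6000:6005] + 8 * sd(x) * shape
  y2 <- despike(xs2, fs)
  expect_true(all(abs(y2 - median(y2)) <= 5 * sd(x) + 1))
  expect_warning(despike(c(rnorm(100), rep(50, 40)), 100), "quality")
})

test_that("resampling and detrending meet their contracts", {
  expect_error(resample_1024(rnorm(100), 512), "1024")
  x <- tone(12, 4, 2048)
  y <- resample_1024(x, 2048)
  expect_equal(length(y), length(x) / 2)
  expect_lt(abs(max(abs(y[500:3500])) - 1), 0.01)
  expect_identical(resample_1024(x, 1024), x)
  # detrend: constant -> ~0, 12 Hz within 1 dB, 0.05 Hz down >= 20 dB
  fs <- 256
  expect_lt(max(abs(detrend_hp(rep(2, 5000), fs))), 1e-8)
  s12 <- tone(12, 20, fs)
  expect_gt(20 * log10(sd(detrend_hp(s12, fs)) / sd(s12)), -1)
  slow <- tone(0.05, 120, fs)
  expect_lt(20 * log10(sd(detrend_hp(slow, fs)) / sd(slow)), -20)
})

test_that("sigma bandpass isolates 10-16 Hz", {
  fs <- 1024
  s13 <- tone(13, 10, fs)
  expect_gt(20 * log10(sd(sigma_bandpass(s13, fs)) / sd(s13)), -1)
  expect_lt(sd(sigma_bandpass(tone(4, 10, fs), fs)) / sd(tone(4, 10, fs)), 0.1)
  expect_lt(sd(sigma_bandpass(tone(25, 10, fs), fs)) / sd(tone(25, 10, fs)), 0.1)
  # filtered white noise concentrates its power in 9-17 Hz
  set.seed(2)
  fn <- sigma_bandpass(rnorm(60 * fs), fs)
  ps <- welch_psd(fn, fs, fmin = 0, fmax = Inf)
  tot <- band_power(ps, c(0, fs / 2))
  expect_gt(band_power(ps, c(9, 17)) / tot, 0.9)
})

test_that("detect_spindles recovers a planted burst only inside NREM", {
  fs <- 1024
  hyp <- hypnogram(c("WAKE", "NREM", "NREM", "NREM", "WAKE"))
  n <- 5 * 4 * fs
  set.seed(3)
  bg <- sigma_bandpass(rnorm(n, sd = 1), fs)
  expect_equal(nrow(detect_spindles(numeric(n), fs, hyp)), 0)
  burst <- function(at, dur, snr) {
    idx <- round(at * fs):(round((at + dur) * fs) - 1)
    env <- ecogsleep:::hann_window(length(idx))
    out <- numeric(n)
    out[idx] <- snr * sd(bg) * env * sin(2 * pi * 13 * (idx / fs))
    out
  }
  # 1-s burst at SNR 5 inside NREM: one event within 0.1 s of truth
  x <- bg + burst(9.0, 1.0, 5)
  ev <- detect_spindles(x, fs, hyp)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$start_s - 9.0), 0.1)
  expect_lt(abs(ev$end_s - 10.0), 0.1)
  # same burst in a WAKE epoch: clipped away entirely
  xw <- bg + burst(1.0, 1.0, 5)
  expect_equal(nrow(detect_spindles(xw, fs, hyp)), 0)
  expect_error(detect_spindles(x, fs, hypnogram(rep("WAKE", 5))), "baseline")
})

test_that("event metrics behave like the definitions", {
  fs <- 1024
  x <- tone(13, 20, fs, amp = 0.7)
  ev <- data.frame(channel_id = "ch01", start_s = 10.0, end_s = 11.2)
  m <- event_metrics(ev, x, fs)
  expect_equal(m$amplitude, 2 * 0.7, tolerance = 0.01)  # max - min of a sinusoid
  expect_equal(m$duration, 1.2)
  m2 <- event_metrics(ev, 2 * x, fs)
  expect_equal(m2$amplitude / m$amplitude, 2, tolerance = 1e-9)
  expect_equal(m2$power / m$power, 4, tolerance = 1e-9)  # homogeneity
})

test_that("density is the exact event/NREM-seconds ratio", {
  ev <- data.frame(channel_id = "c", start_s = 1:12, end_s = 1:12 + 0.5)
  expect_identical(spindle_density(ev, 60), 12 / 60)
  expect_identical(spindle_density(ev[0, ], 60), 0)
  expect_error(spindle_density(ev, 0), "positive")
})

test_that("the pipeline recovers planted spindles and their amplitudes", {
  sim <- small_sim()
  gt <- sim$ground_truth$spindle_events
  res <- spindle_pipeline(sim$recording, sim$ground_truth$hypnogram,
                          channels = c("ch01", "ch02"))
  gt2 <- gt[gt$channel_id %in% c("ch01", "ch02"), ]
  m <- match_events(res$events, gt2)
  expect_gte(m$precision, 0.9)
  expect_gte(m$recall, 0.9)
  # density within 3 Poisson SDs of the configured rate
  nrem_s <- res$summary$nrem_duration
  rate <- sim$ground_truth$config$spindle_rate
  dens <- nrow(gt2[gt2$channel_id == "ch01", ]) / nrem_s
  expect_lt(abs(dens - rate), 3 * sqrt(rate / nrem_s))
  expect_identical(res$summary$density,
                   nrow(res$events) / res$summary$nrem_duration)
  # amplitude of matched events ~ 2x planted peak (max - min of the burst)
  med_amp <- median(res$events$amplitude)
  expect_lt(abs(med_amp - 2 * gt2$amplitude[1]) / (2 * gt2$amplitude[1]), 0.25)
  # idempotence: despiking an already despiked channel changes nothing
  x <- despike(sim$recording$samples["ch01", ], sim$recording$fs)
  expect_lt(mean(as.numeric(despike(x, sim$recording$fs)) != as.numeric(x)), 0.001)
})

test_that("ICA mode runs and maps events back to channels", {
  sim <- small_sim()
  set.seed(1)
  res <- spindle_pipeline(sim$recording, sim$ground_truth$hypnogram,
                          channels = sim$recording$channel_ids,
                          use_ica = TRUE, n_components = 4)
  expect_true(all(res$events$channel_id %in% sim$recording$channel_ids))
  expect_true(all(res$events$end_s > res$events$start_s))
})
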