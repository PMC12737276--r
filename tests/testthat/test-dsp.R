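# Contracts of the hand-rolled DSP layer: filter magnitude responses,
# zero-phase behavior, Welch estimator against a brute-force periodogram
# oracle, Hilbert envelope, and polyphase resampling.

test_that("Butterworth designs meet their magnitude contracts", {
  fs <- 1024
  bp <- butter_design(5, c(10, 16), fs, "pass")
  mag <- function(sos, f) Mod(ecogsleep:::sos_freq_response(sos, f, fs))
  # passband center within 1 dB, band edges at -3 dB, stopband >= 20 dB
  expect_gt(20 * log10(mag(bp, 13)), -1)
  expect_equal(mag(bp, c(10, 16)), c(1, 1) / sqrt(2), tolerance = 1e-6)
  expect_lt(20 * log10(mag(bp, 5)), -20)
  expect_lt(20 * log10(mag(bp, 25)), -20)
  hp <- butter_design(2, 0.5, fs, "high")
  expect_equal(mag(hp, 0.5), 1 / sqrt(2), tolerance = 1e-6)
  expect_lt(20 * log10(mag(hp, 0.05)), -20)  # two octaves down
  expect_gt(20 * log10(mag(hp, 12)), -1)
  expect_error(butter_design(2, 600, fs, "low"), "Nyquist")
})

test_that("zero-phase filtering preserves symmetry and kills transients", {
  fs <- 512
  hp <- butter_design(2, 0.5, fs, "high")
  # constant input -> ~0 (DC removal), despite poles near the unit circle
  expect_lt(max(abs(sos_filtfilt(hp, rep(5, 4000)))), 1e-8)
  # symmetric input -> symmetric output (no group delay)
  x <- exp(-((1:4001) - 2001)^2 / 2000) * cos(2 * pi * 15 * ((1:4001) - 2001) / fs)
  y <- sos_filtfilt(butter_design(5, c(10, 16), fs, "pass"), x)
  expect_lt(max(abs(y - rev(y))), 1e-6 * max(abs(y)))
})

test_that("Welch matches a brute-force segment-periodogram average", {
  fs <- 64
  set.seed(1)
  x <- rnorm(fs * 10)
  ws <- ecogsleep:::welch_spectra(x, fs = fs, window_s = 2, overlap_s = 1)
  # oracle: explicit loop over segments, plain periodograms
  nper <- 2 * fs; step <- nper - fs
  w <- ecogsleep:::hann_window(nper)
  starts <- seq(1, length(x) - nper + 1, by = step)
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + nper - 1)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(fft(seg)[1:(nper / 2 + 1)])^2
  }
  dbl <- rep(2, nper / 2 + 1); dbl[c(1, nper / 2 + 1)] <- 1
  oracle <- acc / length(starts) / (fs * sum(w^2)) * dbl
  expect_equal(ws$pxx, oracle, tolerance = 1e-12)
  expect_equal(ws$n_segments, length(starts))
})

test_that("Hilbert envelope recovers an amplitude modulation", {
  fs <- 256
  t <- (0:(fs * 20 - 1)) / fs
  am <- 1 + 0.5 * sin(2 * pi * 0.5 * t)
  env <- Mod(hilbert_analytic(am * sin(2 * pi * 13 * t)))
  core <- seq(fs, length(t) - fs)
  expect_lt(max(abs(env[core] - am[core])), 0.01)
})

test_that("rational resampling preserves passband sinusoids", {
  fs <- 2048
  x <- tone(12, 10, fs)
  y <- ecogsleep:::resample_rational(x, 1, 2)
  expect_equal(length(y), length(x) / 2)
  core <- 1000:9000
  expect_lt(abs(max(abs(y[core])) - 1), 0.01)
  # non-integer ratio
  y2 <- ecogsleep:::resample_rational(tone(12, 10, 2500), 1024, 2500)
  expect_equal(length(y2), 10 * 1024)
  expect_lt(abs(max(abs(y2[core])) - 1), 0.01)
})

test_that("FastICA recovers mixed super-Gaussian sources", {
  set.seed(11)
  n <- 8000
  S <- matrix(sign(rnorm(8 * n)) * rexp(8 * n), 8)
  A <- matrix(rnorm(16 * 8), 16)
  X <- A %*% S
  set.seed(12)
  dec <- fast_ica(X, n_components = 8)
  co <- abs(cor(t(dec$sources), t(S)))
  expect_gt(min(apply(co, 2, max)), 0.95)
  # mixing %*% sources reconstructs the retained subspace projection
  Xc <- X - rowMeans(X)
  expect_lt(sqrt(sum((dec$mixing %*% dec$sources - Xc)^2) / sum(Xc^2)), 1e-8)
  # determinism under a fixed RNG state
  set.seed(12)
  dec2 <- fast_ica(X, n_components = 8)
  expect_identical(dec$unmixing, dec2$unmixing)
})
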