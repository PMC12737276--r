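# Coherence: |Pxy|^2/(Pxx Pyy) after bandpass + notch, six-band averages,
# pairwise matrices, scale invariance, estimator convergence to the
# coupled-pair closed form, and the paired Wilcoxon + FDR change table.

test_that("self-coherence is 1 and independent noise stays near zero", {
  fs <- 512
  set.seed(1)
  x <- rnorm(20 * fs)
  cs <- msc(x, x, fs = fs)
  inb <- cs$freqs >= 1 & cs$freqs <= 150
  expect_true(all(abs(cs$msc[inb] - 1) < 1e-10))
  # two independent streams, 64 Welch segments: mean msc bounded by bias
  set.seed(2)
  a <- rnorm(65 * fs); b <- rnorm(65 * fs)
  ci <- msc(a, b, fs = fs)
  expect_lte(ci$n_segments, 65)
  expect_gte(ci$n_segments, 63)
  expect_lt(mean(ci$msc[ci$freqs >= 1 & ci$freqs <= 150]), 0.1)
  expect_error(msc(a, b[-1], fs = fs), "equal length")
  expect_error(msc(a[seq_len(2.5 * fs)], b[seq_len(2.5 * fs)], fs = fs), "2 segments")
})

test_that("msc is symmetric and invariant to channel scaling", {
  fs <- 256
  set.seed(3)
  s <- rnorm(30 * fs)
  x <- s + rnorm(30 * fs); y <- 0.6 * s + rnorm(30 * fs)
  c1 <- msc(x, y, fs = fs)
  expect_equal(msc(y, x, fs = fs)$msc, c1$msc, tolerance = 1e-12)
  expect_equal(msc(5 * x, -0.2 * y, fs = fs)$msc, c1$msc, tolerance = 1e-9)
  expect_true(all(c1$msc >= 0 & c1$msc <= 1))
})

test_that("band_coherence averages in-band bins", {
  spec <- structure(list(freqs = seq(0, 256, 0.5),
                         msc = rep(0.5, 513), in_band = c(1, 150)),
                    class = "coherence_spectrum")
  for (b in band_set()$band) expect_equal(band_coherence(spec, b), 0.5)
  spec$msc[] <- 1
  expect_equal(band_coherence(spec, "beta"), 1)
  expect_error(band_coherence(spec, c(200, 250)), "outside")
})

test_that("estimated coherence converges to the coupled-pair closed form", {
  fs <- 256
  set.seed(7)
  base <- rnorm(260 * fs)
  mp <- make_coupled_pair(base, a = 0.8, noise_sd = 1, fs = fs, source = "white")
  expected <- mean(mp$expected_msc)
  errs <- vapply(c(16, 64, 256), function(nseg) {
    n <- (nseg + 1) * fs  # 2-s windows, 50% overlap
    cs <- msc(mp$x[1:n], mp$y[1:n], fs = fs, preprocess = FALSE)
    abs(mean(cs$msc[cs$freqs > 2 & cs$freqs < 120]) - expected)
  }, 0)
  expect_lt(errs[2], 0.05)
  expect_lt(errs[3], errs[1])  # shrinking error with segment count
})

test_that("pairwise_band_matrix is symmetric with unit diagonal", {
  fs <- 256
  set.seed(5)
  s <- rnorm(40 * fs)
  rec <- recording(rbind(s, s, rnorm(40 * fs)), fs = fs,
                   channel_ids = c("a", "dup", "noise"))
  m <- pairwise_band_matrix(rec, "alpha")
  expect_identical(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 3))
  expect_gt(m["a", "dup"], 0.99)      # duplicated channel
  expect_lt(m["a", "noise"], 0.25)    # independent channel, few segments
  expect_true(all(m >= 0 & m <= 1))
  expect_error(pairwise_band_matrix(rec, "alpha", channels = c("a", "zz")), "zz")
  expect_error(pairwise_band_matrix(rec, "alpha", channels = "a"), "2 channels")
})

test_that("compare_conditions classifies paired shifts with exact Wilcoxon", {
  grid <- expand.grid(pair = c("p1", "p2"), band = c("alpha", "beta"),
                      segment = 1:20, stringsAsFactors = FALSE)
  set.seed(8)
  before <- cbind(grid, value = runif(nrow(grid), 0.2, 0.4))
  # identical conditions: degenerate, direction none
  same <- compare_conditions(before, before)
  expect_true(all(same$direction == "none"))
  expect_true(all(same$p_raw == 1))
  # strictly positive (untied) shift: all-one-signed ranks, exact p = 2/2^20
  after <- before
  after$value <- after$value + runif(nrow(after), 0.01, 0.05)
  res <- compare_conditions(before, after)
  expect_true(all(res$direction == "increase"))
  expect_equal(res$p_raw, rep(2 / 2^20, 4), tolerance = 1e-10)  # exact signed-rank oracle
  expect_true(all(res$p_raw < 0.001))
  expect_true(all(res$stars == "***"))
  # unmatched rows error
  expect_error(compare_conditions(before, after[-1, ]), "unmatched")
  short <- before[before$segment <= 3, ]
  expect_error(compare_conditions(short, short), ">= 5")
})
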