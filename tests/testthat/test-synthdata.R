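# The generator's stated world: epoch Markov chain, stage-band dominance,
# NREM-confined spindles, closed-form coupled-pair coherence, line noise,
# spikes, wake-locked motion. Oracles: eigen-decomposition stationary
# distribution, Poisson quantiles, brute-force cross-spectra.

test_that("simulate_hypnogram follows the chain and its stationary law", {
  # absorbing chain: identity transitions keep the start stage
  cfg <- sim_config(duration = 40, stage_transition_weights = diag(3),
                    start_stage = "WAKE", seed = 1)
  expect_equal(as.character(simulate_hypnogram(cfg)$labels), rep("WAKE", 10))
  # epoch count
  cfg2 <- sim_config(duration = 3600, seed = 1)
  expect_length(simulate_hypnogram(cfg2)$labels, 900)
  expect_error(sim_config(duration = 3), "epoch")
  # empirical frequencies within 3 pp of the eigen-decomposition oracle;
  # bouts last 12-30 epochs, so the chain needs ~2e4 epochs before the
  # Monte Carlo error of stage frequencies drops safely below 3 pp
  cfg3 <- sim_config(duration = 20000 * 4, seed = 7)
  hyp <- simulate_hypnogram(cfg3)
  pi_hat <- table(factor(hyp$labels, ecogsleep:::STAGE_LEVELS)) / 20000
  P <- cfg3$stage_transition_weights
  ev <- eigen(t(P))
  pi_star <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  pi_star <- pi_star / sum(pi_star)
  expect_lt(max(abs(as.numeric(pi_hat) - pi_star)), 0.03)
  # reproducible under fixed seed
  expect_identical(simulate_hypnogram(cfg3)$labels, hyp$labels)
})

test_that("stage signals carry their band's dominant power", {
  fs <- 2048
  powers <- function(stage) {
    set.seed(42)
    x <- synth_stage_signal(stage, 4 * fs, fs)
    ps <- welch_psd(x, fs, window_s = 1, overlap_s = 0.5, fmin = 0, fmax = Inf)
    c(nrem = band_power(ps, c(0.5, 4)), rem = band_power(ps, c(6.25, 9)),
      wake = band_power(ps, c(8, 30)))
  }
  p <- powers("NREM")
  expect_true(p["nrem"] > p["rem"] && p["nrem"] > p["wake"])
  p <- powers("WAKE")
  expect_true(p["wake"] > p["nrem"] && p["wake"] > p["rem"])
  p <- powers("REM")
  expect_true(p["rem"] > p["nrem"] && p["rem"] > p["wake"])
  expect_error(synth_stage_signal("SWS", 100, fs), "unknown stage")
  # identical RNG state -> identical vectors; zero mean
  set.seed(5); a <- synth_stage_signal("NREM", 1000, 512)
  set.seed(5); b <- synth_stage_signal("NREM", 1000, 512)
  expect_identical(a, b)
  expect_lt(abs(mean(a)), 1e-12)
})

test_that("embed_spindles plants NREM-confined, duration-gated bursts", {
  fs <- 400
  cfg <- sim_config(fs = fs, duration = 800, spindle_rate = 0.1, seed = 2)
  # all-WAKE hypnogram: warning, empty list, signal untouched
  hw <- hypnogram(rep("WAKE", 200))
  set.seed(1); x <- rnorm(200 * 4 * fs)
  expect_warning(res <- embed_spindles(x, hw, cfg), "no NREM")
  expect_identical(res$signal, x)
  expect_equal(nrow(res$events), 0)
  # NREM-only: Poisson count oracle and duration/containment invariants
  hn <- hypnogram(rep("NREM", 150))  # 600 s NREM
  set.seed(8); xn <- rnorm(150 * 4 * fs)
  set.seed(9); res <- embed_spindles(xn, hn, cfg)
  lam <- 0.1 * 600
  expect_gte(nrow(res$events), qpois(0.005, lam))
  expect_lte(nrow(res$events), qpois(0.995, lam))
  dur <- res$events$end_s - res$events$start_s
  expect_true(all(dur >= 0.4 & dur <= 3.0))
  # each event fully inside one NREM epoch
  expect_true(all(floor(res$events$start_s / 4) == floor((res$events$end_s - 1e-9) / 4)))
  # no overlaps
  o <- order(res$events$start_s)
  expect_true(all(diff(res$events$start_s[o]) >=
                  (res$events$end_s[o] - res$events$start_s[o])[-length(o)]))
})

test_that("make_coupled_pair returns the analytic coherence", {
  fs <- 256; n <- 40 * fs
  set.seed(3)
  base <- rnorm(n)
  # a = 0: no shared source
  mp0 <- make_coupled_pair(base, a = 0, noise_sd = 1, fs = fs, source = "white")
  expect_true(all(mp0$expected_msc == 0))
  # noise -> 0, a = 1: coherence -> 1
  mp1 <- make_coupled_pair(base, a = 1, noise_sd = 1e-6, fs = fs, source = "white")
  expect_true(all(mp1$expected_msc > 0.999))
  # white source, a = 1, noise variance = source variance: msc = 1/4
  mp <- make_coupled_pair(base, a = 1, noise_sd = sd(base), fs = fs, source = "white")
  expect_equal(mean(mp$expected_msc), 0.25, tolerance = 0.01)
  expect_error(make_coupled_pair(base, a = -0.1, noise_sd = 1, fs = fs), "\\[0, 1\\]")
  # closed form matches a brute-force cross-spectral computation within 0.02
  set.seed(4)
  long <- rnorm(200 * fs)
  mpl <- make_coupled_pair(long, a = 0.7, noise_sd = 1, fs = fs, source = "white")
  cs <- msc(mpl$x, mpl$y, fs = fs, preprocess = FALSE)
  sel <- cs$freqs > 2 & cs$freqs < 120
  expect_lt(abs(mean(cs$msc[sel]) - mean(mpl$expected_msc)), 0.02)
})

test_that("simulate_recording is deterministic with coherent ground truth", {
  cfg <- sim_config(n_channels = 2, fs = 400, duration = 600,
                    spike_rate = 2, seed = 1)
  s1 <- simulate_recording(cfg)
  s2 <- simulate_recording(cfg)
  expect_identical(s1$recording$samples, s2$recording$samples)
  expect_identical(s1$ground_truth$spindle_events, s2$ground_truth$spindle_events)
  # planted motion epochs == WAKE epochs elementwise
  expect_identical(as.vector(s1$ground_truth$motion_epochs),
                   as.vector(s1$ground_truth$hypnogram$labels == "WAKE"))
  # spike count within the Poisson central 99% interval (2/min x 10 min x 2 ch)
  k <- nrow(s1$ground_truth$spike_times)
  expect_gte(k, qpois(0.005, 40)); expect_lte(k, qpois(0.995, 40))
  # planted spindles inside NREM epochs
  ev <- s1$ground_truth$spindle_events
  et <- ecogsleep:::epoch_times(s1$ground_truth$hypnogram)
  for (i in seq_len(nrow(ev))) {
    ep <- et[et$start_s <= ev$start_s[i] & et$end_s >= ev$end_s[i], ]
    expect_true(any(ep$stage == "NREM"))
  }
})

test_that("motion frames move only across wake epochs", {
  hyp <- hypnogram(c("NREM", "NREM", "WAKE", "NREM", "NREM"))
  set.seed(6)
  fr <- simulate_motion_frames(hyp, noise_sd = 0.5)
  d <- vapply(2:5, function(e) max(abs(fr[, , e] - fr[, , e - 1])), 0)
  expect_gt(d[2], 20)            # into the WAKE epoch
  expect_lt(max(d[-2]), 5)       # static elsewhere (noise only)
  set.seed(6)
  expect_identical(fr, simulate_motion_frames(hyp, noise_sd = 0.5))
  expect_error(simulate_motion_frames(hyp, frame_size = c(16, 64)), "32")
})
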