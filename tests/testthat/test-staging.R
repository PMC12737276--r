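# Staging: motion detection on synthetic frames, in-epoch STFT band
# powers, the motion-overrides-spectra classification rule, and stage
# proportions.

test_that("detect_motion flags exactly the displacement epochs", {
  hyp <- hypnogram(rep("NREM", 6))
  set.seed(2)
  static <- simulate_motion_frames(hyp, noise_sd = 0.5)
  expect_false(any(detect_motion(static)))
  # threshold above the dynamic range: nothing moves
  one <- hypnogram(c("NREM", "NREM", "WAKE", "NREM"))
  set.seed(3)
  fr <- simulate_motion_frames(one)
  expect_false(any(detect_motion(fr, diff_threshold = 1e6)))
  # single WAKE epoch among NREM: exactly that flag set
  expect_identical(as.vector(detect_motion(fr)), c(FALSE, FALSE, TRUE, FALSE))
  # flags match planted ground truth on a simulated hypnogram
  sim <- small_sim()
  set.seed(9)
  frames <- simulate_motion_frames(sim$ground_truth$hypnogram)
  flags <- detect_motion(frames)
  expect_identical(as.vector(flags), as.vector(sim$ground_truth$motion_epochs))
  expect_error(detect_motion(fr, roi = c(1, 200, 1, 10)), "roi")
})

test_that("epoch_band_powers resolves sinusoid dominance", {
  fs <- 512
  rec2 <- recording(rbind(tone(2, 8, fs), tone(2, 8, fs)), fs = fs)
  bp <- epoch_band_powers(rec2)
  expect_equal(nrow(bp), 2)
  expect_true(all(bp[, "NREM"] > bp[, "WAKE"] & bp[, "NREM"] > bp[, "REM"]))
  rec20 <- recording(matrix(tone(20, 4, fs), 1), fs = fs)
  bp20 <- epoch_band_powers(rec20)
  expect_true(bp20[1, "WAKE"] > max(bp20[1, c("NREM", "REM")]))
  z <- epoch_band_powers(recording(matrix(0, 1, 4 * fs), fs = fs))
  expect_true(all(z == 0))
  expect_error(epoch_band_powers(recording(matrix(0, 1, 100), fs = fs)),
               "shorter")
})

test_that("classification fuses motion and spectral dominance", {
  bp <- cbind(WAKE = c(1, 1), NREM = c(5, 5), REM = c(2, 2))
  # motion true everywhere -> WAKE regardless of spectra
  expect_equal(as.character(classify_epochs(bp, motion = c(TRUE, TRUE))$labels),
               c("WAKE", "WAKE"))
  # delta-dominant without motion -> NREM
  expect_equal(as.character(classify_epochs(bp)$labels), c("NREM", "NREM"))
  # ties break NREM > REM > WAKE
  tie <- cbind(WAKE = 3, NREM = 3, REM = 3)
  expect_equal(as.character(classify_epochs(tie)$labels), "NREM")
  expect_warning(h0 <- classify_epochs(cbind(WAKE = 0, NREM = 0, REM = 0)),
                 "all-zero")
  expect_equal(as.character(h0$labels), "WAKE")
  expect_error(classify_epochs(bp, motion = TRUE), "length")
})

test_that("staging recovers the planted hypnogram and is channel-order stable", {
  sim <- small_sim()
  hyp <- stage_recording(sim$recording)
  expect_gt(mean(hyp$labels == sim$ground_truth$hypnogram$labels), 0.95)
  # permutation stability: channel order must not matter
  perm <- rev(sim$recording$channel_ids)
  hyp2 <- stage_recording(sim$recording, channels = perm)
  expect_identical(hyp$labels, hyp2$labels)
})

test_that("stage proportions normalize to 100", {
  expect_equal(stage_proportions(hypnogram(c("WAKE", "WAKE", "NREM", "REM"))),
               c(WAKE = 50, NREM = 25, REM = 25))
  expect_equal(unname(stage_proportions(hypnogram(rep("NREM", 7)))),
               c(0, 100, 0))
  set.seed(1)
  p <- stage_proportions(hypnogram(sample(c("WAKE", "NREM", "REM"), 101, TRUE)))
  expect_equal(sum(p), 100)
})
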