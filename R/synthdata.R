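# Synthetic-data generator. Emits multichannel grid recordings with a known
# (planted) hypnogram, spindle events, pairwise coherence structure, line
# noise, transient spikes and a per-epoch motion surrogate, so every stage
# of the analysis pipeline can be scored against ground truth.
#
# The stated world of the generator: 4-s staging epochs over WAKE/NREM/REM;
# stage-dependent spectral dominance (delta 0.5-4 Hz in NREM, 6.25-9 Hz in
# REM, 8-30 Hz in wake); Hann-windowed sigma-band (10-16 Hz) spindle bursts
# confined to NREM; mains interference at 50/100/150 Hz; sparse biphasic
# spikes large enough to trip a 5-SD excision rule; and motion that exists
# only in wake epochs.

EPOCH_LEN <- 4

#' Simulation configuration
#'
#' @param n_channels number of electrode channels (default 64, the 8x8 grid).
#' @param fs sampling rate in Hz; must exceed 300 so that 150 Hz mains
#'   content exists below Nyquist.
#' @param duration recording length in seconds.
#' @param stage_dwell_means named mean bout durations (s) per stage; used to
#'   derive the default epoch-level transition matrix.
#' @param stage_transition_weights 3x3 row-stochastic matrix over
#'   WAKE/NREM/REM at the 4-s epoch step; overrides `stage_dwell_means`.
#' @param start_stage initial stage of the Markov chain.
#' @param spindle_rate planted spindle events per second of NREM.
#' @param spindle_freq burst carrier frequency in Hz (10-16).
#' @param spindle_amp_snr burst peak amplitude as a multiple of the
#'   channel's background RMS.
#' @param spindle_dur_range planted duration range in seconds, within
#'   `[0.4, 3]` so every planted event satisfies the detector's own gate.
#' @param stage_osc_amp amplitude of the stage-band oscillation (the 1/f
#'   background has unit variance, so the default 2 makes the stage band
#'   carry most of the epoch power).
#' @param line_noise_amp named amplitudes of the 50/100/150 Hz mains lines.
#' @param spike_rate transient artifacts per minute per channel.
#' @param spike_snr spike peak as a multiple of the channel SD (default 8,
#'   comfortably beyond the 5-SD excision rule).
#' @param coupling_pairs list of `list(i =, j =, a =)` entries: channel `j`
#'   becomes `a` times channel `i`'s source plus independent noise, giving
#'   a closed-form expected coherence.
#' @param coupling_noise_sd SD of the independent noise added to each
#'   member of a coupled pair.
#' @param seed integer RNG seed; every simulator output is a pure function
#'   of (config, seed).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_channels = 64, fs = 2048, duration = 600,
                       stage_dwell_means = c(WAKE = 100, NREM = 120, REM = 50),
                       stage_transition_weights = NULL,
                       start_stage = "WAKE",
                       spindle_rate = 0.1, spindle_freq = 13,
                       spindle_amp_snr = 3,
                       spindle_dur_range = c(0.5, 2.0),
                       stage_osc_amp = 2,
                       line_noise_amp = c(`50` = 0.2, `100` = 0.1, `150` = 0.05),
                       spike_rate = 1, spike_snr = 8,
                       coupling_pairs = list(),
                       coupling_noise_sd = 1,
                       seed = 1) {
  if (fs <= 300) stop("fs must exceed 300 Hz so 150 Hz content exists")
  if (duration < EPOCH_LEN) stop("duration must cover at least one 4-s epoch")
  if (spindle_freq < 10 || spindle_freq > 16)
    stop("spindle_freq must lie in the sigma band (10-16 Hz)")
  if (spindle_dur_range[1] < 0.4 || spindle_dur_range[2] > 3.0 ||
      diff(spindle_dur_range) < 0)
    stop("spindle_dur_range must be an increasing interval within [0.4, 3]")
  if (is.null(stage_transition_weights))
    stage_transition_weights <- dwell_to_transition(stage_dwell_means)
  P <- as.matrix(stage_transition_weights)
  if (!all(dim(P) == c(3, 3)) || any(P < 0) ||
      any(abs(rowSums(P) - 1) > 1e-8))
    stop("stage_transition_weights must be a 3x3 row-stochastic matrix")
  dimnames(P) <- list(STAGE_LEVELS, STAGE_LEVELS)
  for (cp in coupling_pairs) {
    if (cp$a < 0 || cp$a > 1) stop("mixing coefficient must lie in [0, 1]")
    if (cp$i == cp$j || cp$i > n_channels || cp$j > n_channels)
      stop("coupling pair channels out of range")
  }
  if (!start_stage %in% STAGE_LEVELS) stop("unknown start_stage")
  structure(list(n_channels = n_channels, fs = fs, duration = duration,
                 stage_transition_weights = P, start_stage = start_stage,
                 spindle_rate = spindle_rate, spindle_freq = spindle_freq,
                 spindle_amp_snr = spindle_amp_snr,
                 spindle_dur_range = spindle_dur_range,
                 stage_osc_amp = stage_osc_amp,
                 line_noise_amp = line_noise_amp,
                 spike_rate = spike_rate, spike_snr = spike_snr,
                 coupling_pairs = coupling_pairs,
                 coupling_noise_sd = coupling_noise_sd,
                 seed = seed),
            class = "sim_config")
}

# Epoch-step transition matrix from mean bout durations: the stay
# probability is 1 - epoch/dwell; leaving mass follows mouse-like routing
# (wake almost never enters REM directly; REM mostly ends in wake).
dwell_to_transition <- function(dwell) {
  stay <- pmax(0, 1 - EPOCH_LEN / dwell[STAGE_LEVELS])
  route <- rbind(WAKE = c(0, 0.98, 0.02),
                 NREM = c(0.40, 0, 0.60),
                 REM  = c(0.85, 0.15, 0))
  P <- route * (1 - stay)
  diag(P) <- stay
  colnames(P) <- STAGE_LEVELS
  P
}

# Stationary distribution of a row-stochastic matrix (left eigenvector).
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v <- v / sum(v)
  stats::setNames(v, rownames(P))
}

# Run body with a private RNG stream, restoring the caller's state.
with_local_seed <- function(seed, body) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  body
}

#' Simulate a hypnogram from the stage Markov chain
#'
#' @param config a [sim_config()]. The chain runs at the 4-s epoch step with
#'   the configured transition matrix; output is reproducible for a fixed
#'   `config$seed`.
#' @return an [hypnogram()] with `floor(duration / 4)` epochs.
#' @export
simulate_hypnogram <- function(config) {
  if (config$duration < EPOCH_LEN) stop("duration shorter than one epoch")
  n <- floor(config$duration / EPOCH_LEN)
  with_local_seed(config$seed, {
    P <- config$stage_transition_weights
    states <- character(n)
    s <- config$start_stage
    for (i in seq_len(n)) {
      states[i] <- s
      s <- sample(STAGE_LEVELS, 1, prob = P[s, ])
    }
    hypnogram(states, epoch_len = EPOCH_LEN)
  })
}

#' Synthesize one stage's signal segment
#'
#' Unit-variance 1/f background plus a stage-band oscillation (2 Hz for
#' NREM, 7.5 Hz for REM, 20 Hz for wake) with random phase and a few
#' percent of frequency jitter, drawn from the current RNG state.
#'
#' @param stage one of `"WAKE"`, `"NREM"`, `"REM"`.
#' @param n_samples segment length in samples; `fs` sampling rate in Hz.
#' @param osc_amp oscillation amplitude (see [sim_config()]).
#' @return zero-mean numeric vector of length `n_samples`.
#' @export
synth_stage_signal <- function(stage, n_samples, fs, osc_amp = 2) {
  if (!stage %in% STAGE_LEVELS) stop("unknown stage: ", stage)
  bg <- one_over_f_noise(n_samples, fs)
  f0 <- switch(stage, NREM = 2, REM = 7.5, WAKE = 20)
  f <- f0 * stats::runif(1, 0.95, 1.05)
  phi <- stats::runif(1, 0, 2 * pi)
  t <- (seq_len(n_samples) - 1) / fs
  x <- bg + osc_amp * sin(2 * pi * f * t + phi)
  x - mean(x)
}

# Gaussian noise with a 1/f amplitude rolloff above 0.5 Hz, unit variance.
one_over_f_noise <- function(n, fs, f_knee = 0.5) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)  # fold to two-sided frequency magnitude
  shape <- 1 / sqrt(pmax(f, f_knee))
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  x <- x - mean(x)
  x / stats::sd(x)
}

#' Embed Hann-windowed spindle bursts into NREM epochs
#'
#' Plants `Poisson(rate x NREM seconds)` sigma-band bursts, each fully
#' inside one NREM epoch, non-overlapping (overlaps are resampled), with
#' peak amplitude `spindle_amp_snr` times the signal RMS.
#'
#' @param signal one channel's samples; `hyp` the matching hypnogram.
#' @param config a [sim_config()]; draws come from the current RNG state.
#' @return list with `signal` (bursts added) and `events` (data.frame of
#'   `start_s`, `end_s`, `amplitude`, `freq`).
#' @export
embed_spindles <- function(signal, hyp, config) {
  fs <- config$fs
  et <- epoch_times(hyp)
  nrem <- et[et$stage == "NREM", , drop = FALSE]
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      amplitude = numeric(0), freq = numeric(0))
  if (!nrow(nrem)) {
    if (config$spindle_rate > 0)
      warning("no NREM epochs: no spindles embedded")
    return(list(signal = signal, events = empty))
  }
  nrem_s <- sum(nrem$end_s - nrem$start_s)
  n_ev <- stats::rpois(1, config$spindle_rate * nrem_s)
  amp <- config$spindle_amp_snr * stats::sd(signal)
  placed <- empty
  tries <- 0
  while (nrow(placed) < n_ev && tries < 50 * n_ev + 100) {
    tries <- tries + 1
    dur <- stats::runif(1, config$spindle_dur_range[1],
                        min(config$spindle_dur_range[2], hyp$epoch_len))
    ep <- nrem[sample.int(nrow(nrem), 1), ]
    start <- stats::runif(1, ep$start_s, ep$end_s - dur)
    if (nrow(placed) &&
        any(start < placed$end_s & (start + dur) > placed$start_s)) next
    placed <- rbind(placed, data.frame(start_s = start, end_s = start + dur,
                                       amplitude = amp,
                                       freq = config$spindle_freq))
  }
  if (nrow(placed)) {
    placed <- placed[order(placed$start_s), , drop = FALSE]
    rownames(placed) <- NULL
    for (k in seq_len(nrow(placed))) {
      i0 <- floor(placed$start_s[k] * fs) + 1
      i1 <- min(length(signal), ceiling(placed$end_s[k] * fs))
      idx <- i0:i1
      tt <- (idx - 1) / fs - placed$start_s[k]
      env <- hann_window(length(idx))
      phi <- stats::runif(1, 0, 2 * pi)
      signal[idx] <- signal[idx] +
        placed$amplitude[k] * env * sin(2 * pi * placed$freq[k] * tt + phi)
    }
  }
  list(signal = signal, events = placed)
}

#' Construct a coupled signal pair with closed-form expected coherence
#'
#' Builds `x = s + n1`, `y = a * s + n2` with independent white noises of
#' SD `noise_sd`. For source PSD `Ps(f)` and noise PSD `Pn`, the expected
#' magnitude-squared coherence is `a^2 Ps^2 / ((Ps + Pn) (a^2 Ps + Pn))`.
#'
#' @param base the shared source signal `s`.
#' @param a mixing coefficient in `[0, 1]`; `noise_sd` noise SD (> 0).
#' @param fs sampling rate, used to evaluate the source PSD on the Welch
#'   frequency grid; `window_s` the Welch window for that grid.
#' @param source one of `"welch"` (estimate `Ps` from the supplied
#'   realization) or `"white"` (treat the source as white with variance
#'   `var(base)`, giving a frequency-flat closed form).
#' @return list `x`, `y`, `freqs`, `expected_msc`.
#' @export
make_coupled_pair <- function(base, a, noise_sd, fs, window_s = 2,
                              source = c("welch", "white")) {
  source <- match.arg(source)
  if (a < 0 || a > 1) stop("mixing coefficient a must lie in [0, 1]")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  n <- length(base)
  x <- base + stats::rnorm(n, sd = noise_sd)
  y <- a * base + stats::rnorm(n, sd = noise_sd)
  pn <- noise_sd^2 * 2 / fs  # one-sided density of white noise
  if (source == "welch") {
    ws <- welch_spectra(base, fs = fs, window_s = window_s,
                        overlap_s = window_s / 2)
    freqs <- ws$freqs
    ps <- ws$pxx
  } else {
    nper <- round(window_s * fs)
    freqs <- (0:(nper %/% 2)) * fs / nper
    ps <- rep(stats::var(base) * 2 / fs, length(freqs))
  }
  msc <- a^2 * ps^2 / ((ps + pn) * (a^2 * ps + pn))
  list(x = x, y = y, freqs = freqs, expected_msc = msc)
}

#' Simulate a full grid recording with ground truth
#'
#' Assembles, per channel: stage-dependent signal along the planted
#' hypnogram, NREM spindle bursts, mains lines at 50/100/150 Hz (common
#' phase across channels), sparse biphasic spikes, and the configured
#' coupled pairs. Byte-identical output for identical `config`.
#'
#' @param config a [sim_config()].
#' @return list with `recording` (an [recording()]) and `ground_truth`:
#'   `hypnogram`, `spindle_events` (channel_id, start_s, end_s, amplitude),
#'   `spike_times` (channel_id, time_s), `motion_epochs` (logical, TRUE iff
#'   WAKE), and `pair_coherence` (per coupled pair and band, the closed-form
#'   expected coherence plus the per-frequency curve as an attribute).
#' @export
simulate_recording <- function(config) {
  hyp <- simulate_hypnogram(config)
  fs <- config$fs
  n_ep <- length(hyp$labels)
  n <- n_ep * hyp$epoch_len * fs
  with_local_seed(config$seed + 1L, {
    bouts <- rle(as.character(hyp$labels))
    samples <- matrix(0, config$n_channels, n)
    spindle_events <- list()
    coupled_j <- vapply(config$coupling_pairs, function(cp) cp$j, 0)
    for (ch in seq_len(config$n_channels)) {
      pos <- 0
      sig <- numeric(n)
      for (b in seq_along(bouts$lengths)) {
        nb <- bouts$lengths[b] * hyp$epoch_len * fs
        sig[pos + seq_len(nb)] <- synth_stage_signal(
          bouts$values[b], nb, fs, osc_amp = config$stage_osc_amp)
        pos <- pos + nb
      }
      es <- embed_spindles(sig, hyp, config)
      sig <- es$signal
      if (nrow(es$events) && !(ch %in% coupled_j))
        spindle_events[[length(spindle_events) + 1]] <-
          cbind(channel_id = sprintf("ch%02d", ch), es$events)
      samples[ch, ] <- sig
    }
    # coupled pairs: source is channel i's composed signal
    pair_rows <- list()
    bands <- band_set()
    for (cp in config$coupling_pairs) {
      s <- samples[cp$i, ]
      mp <- make_coupled_pair(s, cp$a, config$coupling_noise_sd, fs)
      samples[cp$i, ] <- mp$x
      samples[cp$j, ] <- mp$y
      bm <- vapply(seq_len(nrow(bands)), function(k) {
        sel <- mp$freqs >= bands$low[k] & mp$freqs < bands$high[k]
        mean(mp$expected_msc[sel])
      }, 0)
      pr <- data.frame(i = cp$i, j = cp$j, a = cp$a,
                       band = bands$band, expected_msc = bm)
      attr(pr, "freqs") <- mp$freqs
      attr(pr, "expected_msc_f") <- mp$expected_msc
      pair_rows[[length(pair_rows) + 1]] <- pr
    }
    # mains interference, common phase across channels
    t <- (seq_len(n) - 1) / fs
    for (fl in names(config$line_noise_amp)) {
      f0 <- as.numeric(fl)
      phi <- stats::runif(1, 0, 2 * pi)
      line <- config$line_noise_amp[[fl]] * sin(2 * pi * f0 * t + phi)
      samples <- sweep(samples, 2, line, "+")
    }
    # biphasic transients (5 ms, spike_snr x channel SD)
    spikes <- list()
    half <- max(1, round(0.0025 * fs))
    lobe <- sin(pi * seq_len(half) / (half + 1))
    shape <- c(lobe, -lobe)
    for (ch in seq_len(config$n_channels)) {
      k <- stats::rpois(1, config$spike_rate / 60 * config$duration)
      if (!k) next
      at <- sort(stats::runif(k, 0.01, config$duration - 0.01))
      amp <- config$spike_snr * stats::sd(samples[ch, ])
      for (a0 in at) {
        i0 <- floor(a0 * fs)
        idx <- i0 + seq_along(shape)
        idx <- idx[idx <= n]
        samples[ch, idx] <- samples[ch, idx] + amp * shape[seq_along(idx)]
      }
      spikes[[length(spikes) + 1]] <-
        data.frame(channel_id = sprintf("ch%02d", ch), time_s = at)
    }
    ids <- sprintf("ch%02d", seq_len(config$n_channels))
    lay <- if (config$n_channels == 64) electrode_layout(ids) else NULL
    rec <- recording(samples, fs = fs, channel_ids = ids, layout = lay)
    gt <- list(
      hypnogram = hyp,
      spindle_events = if (length(spindle_events))
        do.call(rbind, spindle_events) else
          data.frame(channel_id = character(0), start_s = numeric(0),
                     end_s = numeric(0), amplitude = numeric(0),
                     freq = numeric(0)),
      spike_times = if (length(spikes)) do.call(rbind, spikes) else
        data.frame(channel_id = character(0), time_s = numeric(0)),
      motion_epochs = hyp$labels == "WAKE",
      pair_coherence = pair_rows,
      config = config)
    list(recording = rec, ground_truth = gt)
  })
}

#' Synthesize per-epoch video frames with wake-locked motion
#'
#' One grayscale frame per epoch: a bright Gaussian blob over pixel noise.
#' The blob jumps to a new position when (and only when) the epoch is WAKE,
#' so supra-noise frame differences occur exactly across wake epochs.
#'
#' @param hyp an [hypnogram()].
#' @param frame_size `c(height, width)` in pixels, each at least 32.
#' @param noise_sd pixel noise SD; `blob_intensity` blob peak intensity.
#' @return `height x width x n_epochs` numeric array.
#' @export
simulate_motion_frames <- function(hyp, frame_size = c(64, 64),
                                   noise_sd = 1, blob_intensity = 120) {
  if (any(frame_size < 32)) stop("frame_size must be at least 32x32")
  h <- frame_size[1]; w <- frame_size[2]
  n <- length(hyp$labels)
  frames <- array(0, c(h, w, n))
  pos <- c(h / 2, w / 2)
  for (e in seq_len(n)) {
    if (hyp$labels[e] == "WAKE") {
      repeat {
        cand <- c(stats::runif(1, h * 0.2, h * 0.8),
                  stats::runif(1, w * 0.2, w * 0.8))
        if (sum((cand - pos)^2) > 25) break  # force a real displacement
      }
      pos <- cand
    }
    rr <- outer((seq_len(h) - pos[1])^2, (seq_len(w) - pos[2])^2, "+")
    frames[, , e] <- blob_intensity * exp(-rr / (2 * 3^2)) +
      matrix(stats::rnorm(h * w, sd = noise_sd), h, w)
  }
  frames
}
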