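# Sleep staging of 4-s epochs. An epoch showing body movement in the video
# surrogate is scored WAKE outright; otherwise the stage whose canonical
# band (wake 8-30 Hz, NREM 0.5-4 Hz, REM 6.25-9 Hz) carries the largest
# summed STFT power wins, ties broken NREM > REM > WAKE.

#' Canonical staging bands
#'
#' Half-open `[low, high)` intervals: wake 8-30 Hz, NREM 0.5-4 Hz,
#' REM 6.25-9 Hz. The REM/wake overlap at 8-9 Hz is intentional and kept.
#'
#' @return data.frame with `stage`, `low`, `high`.
#' @export
stage_bands <- function() {
  data.frame(stage = c("WAKE", "NREM", "REM"),
             low = c(8, 0.5, 6.25), high = c(30, 4, 9),
             stringsAsFactors = FALSE)
}

# 3x3 binary erosion / dilation via shift-stacking
shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

binary_open3 <- function(m) {
  er <- m
  for (dr in -1:1) for (dc in -1:1)
    if (dr || dc) er <- er & shift_mat(m, dr, dc)
  di <- er
  for (dr in -1:1) for (dc in -1:1)
    if (dr || dc) di <- di | shift_mat(er, dr, dc)
  di
}

# size of the largest 8-connected component of a logical matrix
largest_component <- function(m) {
  if (!any(m)) return(0L)
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  best <- 0L; cur <- 0L
  for (p in which(m)) {
    if (lab[p]) next
    cur <- cur + 1L
    queue <- p; lab[p] <- cur; size <- 0L
    while (length(queue)) {
      q <- queue[length(queue)]; queue <- queue[-length(queue)]
      size <- size + 1L
      r <- (q - 1L) %% h + 1L; cc <- (q - 1L) %/% h + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; ccc <- cc + dc
        if (rr >= 1 && rr <= h && ccc >= 1 && ccc <= w) {
          idx <- (ccc - 1L) * h + rr
          if (m[idx] && !lab[idx]) { lab[idx] <- cur; queue <- c(queue, idx) }
        }
      }
    }
    best <- max(best, size)
  }
  best
}

#' Detect per-epoch motion from video frames
#'
#' Consecutive-frame absolute differencing inside a region of interest,
#' thresholding, 3x3 binary opening, and a minimum connected-component
#' size. The first epoch inherits the second epoch's flag (it has no
#' preceding frame).
#'
#' @param frames `height x width x n_epochs` array from a frame extractor
#'   (one frame per 4-s epoch), e.g. [simulate_motion_frames()].
#' @param roi `c(row_min, row_max, col_min, col_max)` or `NULL` for the
#'   full frame.
#' @param diff_threshold intensity difference counted as change.
#' @param min_blob_px smallest connected changed region scored as motion.
#' @return logical vector of per-epoch motion flags with attributes
#'   `threshold` and `roi`.
#' @export
detect_motion <- function(frames, roi = NULL, diff_threshold = 20,
                          min_blob_px = 5) {
  d <- dim(frames)
  if (length(d) != 3 || d[3] < 2) stop("need a h x w x n array with >= 2 frames")
  if (is.null(roi)) roi <- c(1, d[1], 1, d[2])
  if (roi[1] < 1 || roi[2] > d[1] || roi[3] < 1 || roi[4] > d[2] ||
      roi[1] > roi[2] || roi[3] > roi[4])
    stop("roi outside frame bounds")
  n <- d[3]
  flags <- logical(n)
  prev <- frames[roi[1]:roi[2], roi[3]:roi[4], 1]
  for (e in 2:n) {
    cur <- frames[roi[1]:roi[2], roi[3]:roi[4], e]
    changed <- binary_open3(abs(cur - prev) > diff_threshold)
    flags[e] <- largest_component(changed) >= min_blob_px
    prev <- cur
  }
  flags[1] <- flags[2]
  attr(flags, "threshold") <- diff_threshold
  attr(flags, "roi") <- roi
  flags
}

#' Per-epoch summed band powers from an in-epoch STFT
#'
#' Each 4-s epoch is analyzed with 1-s Hann windows at 50% overlap; the
#' modified periodograms are averaged and power is summed over each staging
#' band, then averaged across the selected channels.
#'
#' @param rec an [recording()].
#' @param channels channel ids (or indices) to average over; default all.
#' @param epoch_len epoch length in seconds (must be a whole number of
#'   samples); `bands` a [stage_bands()] table.
#' @param window_s STFT window inside the epoch.
#' @return `n_epochs x 3` matrix with columns `WAKE`, `NREM`, `REM`.
#' @export
epoch_band_powers <- function(rec, channels = NULL, epoch_len = 4,
                              bands = stage_bands(), window_s = 1) {
  fs <- rec$fs
  ns_ep <- epoch_len * fs
  if (ns_ep != round(ns_ep) || ns_ep <= 0)
    stop("epoch_len must be a positive whole number of samples")
  if (ncol(rec$samples) < ns_ep) stop("recording shorter than one epoch")
  if (is.null(channels)) channels <- rec$channel_ids
  if (is.numeric(channels)) channels <- rec$channel_ids[channels]
  n_ep <- ncol(rec$samples) %/% ns_ep
  nwin <- round(window_s * fs)
  step <- nwin %/% 2
  offsets <- seq(1, ns_ep - nwin + 1, by = step)
  w <- hann_window(nwin)
  nfreq <- nwin %/% 2 + 1
  freqs <- (0:(nfreq - 1)) * fs / nwin
  acc <- matrix(0, nfreq, n_ep)
  for (ch in channels) {
    x <- rec$samples[ch, seq_len(n_ep * ns_ep)]
    E <- matrix(x, nrow = ns_ep)          # samples x epochs
    for (o in offsets) {
      seg <- E[o:(o + nwin - 1), , drop = FALSE]
      seg <- (seg - rep(colMeans(seg), each = nwin)) * w
      FX <- stats::mvfft(seg)[1:nfreq, , drop = FALSE]
      acc <- acc + Mod(FX)^2
    }
  }
  acc <- acc / (length(channels) * length(offsets) * sum(w^2))
  bp <- vapply(seq_len(nrow(bands)), function(k) {
    sel <- freqs >= bands$low[k] & freqs < bands$high[k]
    colSums(acc[sel, , drop = FALSE])
  }, numeric(n_ep))
  if (n_ep == 1) bp <- matrix(bp, nrow = 1)
  colnames(bp) <- bands$stage
  bp
}

#' Classify epochs into WAKE/NREM/REM
#'
#' Motion-positive epochs are WAKE regardless of spectra; the rest take the
#' stage with maximal summed band power, ties broken NREM > REM > WAKE.
#' Epochs with all-zero power are labeled WAKE with a warning.
#'
#' @param band_powers matrix from [epoch_band_powers()].
#' @param motion optional logical per-epoch motion flags from
#'   [detect_motion()]; lengths must match.
#' @return an [hypnogram()].
#' @export
classify_epochs <- function(band_powers, motion = NULL) {
  n <- nrow(band_powers)
  if (!is.null(motion) && length(motion) != n)
    stop("motion series length does not match epoch count")
  pref <- c("NREM", "REM", "WAKE")  # tie-break priority
  labs <- character(n)
  zero <- FALSE
  for (e in seq_len(n)) {
    p <- band_powers[e, pref]
    if (all(p == 0)) { labs[e] <- "WAKE"; zero <- TRUE; next }
    labs[e] <- pref[which.max(p)]
  }
  if (zero) warning("epoch(s) with all-zero band power labeled WAKE")
  if (!is.null(motion)) labs[as.logical(motion)] <- "WAKE"
  hypnogram(labs)
}

#' Stage proportions of a hypnogram
#'
#' @param hyp an [hypnogram()].
#' @return named percentages over WAKE/NREM/REM summing to 100.
#' @export
stage_proportions <- function(hyp) {
  tb <- table(hyp$labels)
  100 * as.vector(tb) / sum(tb) -> p
  stats::setNames(p, names(tb))
}

#' Score a recording: motion fusion plus spectral dominance
#'
#' Convenience wrapper: [epoch_band_powers()] then [classify_epochs()],
#' optionally with [detect_motion()] flags from a frame array.
#'
#' @inheritParams epoch_band_powers
#' @param frames optional `h x w x n_epochs` array of video frames.
#' @param ... passed to [detect_motion()].
#' @return an [hypnogram()].
#' @export
stage_recording <- function(rec, channels = NULL, frames = NULL, ...) {
  bp <- epoch_band_powers(rec, channels = channels)
  motion <- if (!is.null(frames)) detect_motion(frames, ...) else NULL
  if (!is.null(motion) && length(motion) != nrow(bp))
    stop("frame count does not match epoch count")
  classify_epochs(bp, motion)
}
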