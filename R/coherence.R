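# Magnitude-squared coherence between channel pairs,
# Cxy(f) = |Pxy(f)|^2 / (Pxx(f) Pyy(f)),
# from segment-averaged Welch cross- and auto-spectra after a 1-150 Hz
# bandpass and 50/100/150 Hz notches; six-band summaries; and the paired
# Wilcoxon + Benjamini-Hochberg change classification between conditions.

#' The six canonical analysis bands
#'
#' delta 1-4, theta 4-8, alpha 8-12, beta 12-30, gamma1 30-80,
#' gamma2 80-150 Hz, as half-open `[low, high)` intervals.
#'
#' @return data.frame with `band`, `low`, `high`.
#' @export
band_set <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta", "gamma1", "gamma2"),
             low = c(1, 4, 8, 12, 30, 80),
             high = c(4, 8, 12, 30, 80, 150),
             stringsAsFactors = FALSE)
}

coherence_preprocess <- function(x, fs, band = c(1, 150),
                                 notches = c(50, 100, 150)) {
  hi <- min(band[2], 0.45 * fs)  # keep the bandpass edge below Nyquist
  sos <- butter_design(4, c(band[1], hi), fs, "pass")
  x <- sos_filtfilt(sos, x, padlen = max(63, round(fs / 2)))
  apply_notch(x, fs, freqs = notches[notches < fs / 2])
}

#' Magnitude-squared coherence spectrum of two signals
#'
#' Both signals are bandpass filtered to 1-150 Hz and notch filtered at
#' 50/100/150 Hz, then cross- and auto-spectra are averaged over Hann
#' segments (default 2-s windows, 50% overlap) and combined as
#' `|Pxy|^2 / (Pxx Pyy)`. Symmetric in its arguments and invariant to
#' per-channel scaling.
#'
#' @param x,y equal-length numeric signals; `fs` sampling rate in Hz.
#' @param window_s,overlap_s Welch segmentation in seconds.
#' @param preprocess set `FALSE` to skip the bandpass/notch stage.
#' @return a `coherence_spectrum`: list with `freqs`, `msc` in `[0,1]`,
#'   `pxx`, `pyy`, `pxy`, `n_segments`, `in_band` (the analysis range).
#' @export
msc <- function(x, y, fs, window_s = 2, overlap_s = window_s / 2,
                preprocess = TRUE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  in_band <- c(1, min(150, 0.45 * fs))
  if (preprocess) {
    x <- coherence_preprocess(x, fs)
    y <- coherence_preprocess(y, fs)
  }
  ws <- welch_spectra(x, y, fs = fs, window_s = window_s,
                      overlap_s = overlap_s)
  if (ws$n_segments < 2)
    stop("need at least 2 segments: coherence of one segment is trivially 1")
  c2 <- Mod(ws$pxy)^2 / (ws$pxx * ws$pyy)
  c2[!is.finite(c2)] <- 0
  structure(list(freqs = ws$freqs, msc = pmin(1, pmax(0, c2)),
                 pxx = ws$pxx, pyy = ws$pyy, pxy = ws$pxy,
                 n_segments = ws$n_segments, in_band = in_band),
            class = "coherence_spectrum")
}

#' Band-average coherence
#'
#' Unweighted mean of the magnitude-squared coherence over bins in the
#' half-open band `[low, high)`.
#'
#' @param spec a `coherence_spectrum`; `band` either a name from
#'   [band_set()] or `c(low, high)` in Hz.
#' @return scalar in `[0, 1]`.
#' @export
band_coherence <- function(spec, band) {
  if (is.character(band)) {
    bs <- band_set()
    if (!band %in% bs$band) stop("unknown band: ", band)
    band <- unlist(bs[bs$band == band, c("low", "high")])
  }
  if (band[1] >= spec$in_band[2] || band[2] <= spec$in_band[1])
    stop("band [", band[1], ", ", band[2], ") lies outside the analysis range [",
         spec$in_band[1], ", ", spec$in_band[2], "] Hz")
  sel <- spec$freqs >= band[1] & spec$freqs < band[2]
  if (!any(sel)) stop("band does not intersect the frequency grid")
  mean(spec$msc[sel])
}

#' Pairwise band-coherence matrix
#'
#' Computes the band-average coherence for every channel pair. Segment
#' FFTs are computed once per channel; the result is exactly symmetric
#' with a unit diagonal.
#'
#' @param rec an [recording()]; `band` as in [band_coherence()].
#' @param channels subset of channel ids or indices (default all).
#' @param window_s,overlap_s Welch segmentation in seconds.
#' @return symmetric matrix with entries in `[0, 1]` and unit diagonal.
#' @export
pairwise_band_matrix <- function(rec, band, channels = NULL,
                                 window_s = 2, overlap_s = window_s / 2) {
  if (is.null(channels)) channels <- rec$channel_ids
  if (is.numeric(channels)) channels <- rec$channel_ids[channels]
  bad <- setdiff(channels, rec$channel_ids)
  if (length(bad)) stop("unknown channel(s): ", paste(bad, collapse = ", "))
  if (length(channels) < 2) stop("need at least 2 channels")
  fs <- rec$fs
  if (is.character(band)) {
    bs <- band_set()
    band <- unlist(bs[bs$band == band, c("low", "high")])
  }
  nper <- round(window_s * fs)
  step <- nper - round(overlap_s * fs)
  w <- hann_window(nper)
  nfreq <- nper %/% 2 + 1
  freqs <- (0:(nfreq - 1)) * fs / nper
  FXs <- lapply(channels, function(ch) {
    x <- coherence_preprocess(rec$samples[ch, ], fs)
    seg <- segment_matrix(x, nper, step)
    seg <- (seg - rep(colMeans(seg), each = nper)) * w
    stats::mvfft(seg)[1:nfreq, , drop = FALSE]
  })
  sel <- freqs >= band[1] & freqs < band[2]
  p <- length(channels)
  auto <- lapply(FXs, function(FX) rowMeans(Mod(FX)^2))
  m <- diag(1, p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    pxy <- rowMeans(Conj(FXs[[i]]) * FXs[[j]])
    c2 <- Mod(pxy)^2 / (auto[[i]] * auto[[j]])
    m[i, j] <- m[j, i] <- mean(pmin(1, c2[sel]))
  }
  dimnames(m) <- list(channels, channels)
  m
}

#' Paired pre/post comparison of band coherences
#'
#' For each (pair, band) cell, a two-sided Wilcoxon matched-pairs
#' signed-rank test on the per-segment coherences (exact null distribution
#' for n <= 25 non-zero differences, continuity-corrected normal
#' approximation otherwise; zero differences dropped), followed by
#' Benjamini-Hochberg FDR correction across all cells. Direction is the
#' sign of the median paired difference; cells with `p_fdr >= alpha` are
#' `"none"`.
#'
#' @param before,after data.frames with columns `pair`, `band`, `segment`,
#'   `value`; matched on all three keys.
#' @param alpha significance level for the direction call (default 0.05).
#' @return data.frame with `pair`, `band`, `n`, `median_diff`, `p_raw`,
#'   `p_fdr`, `direction`, `stars`.
#' @export
compare_conditions <- function(before, after, alpha = 0.05) {
  need <- c("pair", "band", "segment", "value")
  if (!all(need %in% names(before)) || !all(need %in% names(after)))
    stop("before/after need columns: ", paste(need, collapse = ", "))
  m <- merge(before, after, by = c("pair", "band", "segment"),
             suffixes = c("_before", "_after"))
  if (nrow(m) < nrow(before) || nrow(m) < nrow(after))
    stop("unmatched (pair, band, segment) rows between conditions")
  key <- interaction(m$pair, m$band, drop = TRUE)
  out <- lapply(split(m, key), function(g) {
    d <- g$value_after - g$value_before
    if (length(d) < 5) stop("need >= 5 paired observations per pair/band")
    nz <- d[d != 0]
    p <- if (!length(nz)) 1 else {
      suppressWarnings(stats::wilcox.test(
        nz, exact = length(nz) <= 25, correct = TRUE))$p.value
    }
    data.frame(pair = g$pair[1], band = g$band[1], n = length(d),
               median_diff = stats::median(d), p_raw = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$p_fdr <- bh_fdr(res$p_raw)
  res$direction <- ifelse(res$p_fdr >= alpha | res$median_diff == 0, "none",
                          ifelse(res$median_diff > 0, "increase", "decrease"))
  res$stars <- cut(res$p_fdr, c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", ""))
  res
}
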