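# Spectral analysis: mains notch filtering, Welch PSD with 2-s windows and
# 1.75-s overlap, band power, dB transform, and thin-plate-spline RBF
# interpolation of the 8x8 electrode power map to 100x100.

#' Zero-phase notch filtering at the mains harmonics
#'
#' @param x numeric signal; `fs` sampling rate in Hz.
#' @param freqs notch centers in Hz (default 50/100/150).
#' @param q notch quality factor (center / -3 dB width).
#' @return filtered signal, same length.
#' @export
apply_notch <- function(x, fs, freqs = c(50, 100, 150), q = 30) {
  for (f0 in freqs) {
    sos <- notch_design(f0, fs, q)  # errors if f0 >= Nyquist
    x <- sos_filtfilt(sos, x, padlen = max(63, round(fs / 4)))
  }
  x
}

#' Welch power spectral density
#'
#' Averaged modified periodograms of Hann-windowed, per-segment demeaned
#' segments (default 2-s windows with 1.75-s overlap, i.e. 87.5%). The
#' returned grid is restricted to the analysis range.
#'
#' @param x numeric signal; `fs` sampling rate in Hz.
#' @param window_s,overlap_s Welch segmentation in seconds.
#' @param fmin,fmax analysis range in Hz kept in the output (defaults
#'   0.5-150, clamped to Nyquist); use `fmin = 0, fmax = Inf` for the full
#'   one-sided grid.
#' @return a `psd_spectrum`: list with `freqs`, `power` (units^2/Hz),
#'   `window_s`, `overlap_s`, `n_segments`, `db` flag.
#' @export
welch_psd <- function(x, fs, window_s = 2, overlap_s = 1.75,
                      fmin = 0.5, fmax = 150) {
  ws <- welch_spectra(x, fs = fs, window_s = window_s, overlap_s = overlap_s)
  sel <- ws$freqs >= fmin & ws$freqs <= min(fmax, fs / 2)
  structure(list(freqs = ws$freqs[sel], power = ws$pxx[sel],
                 window_s = window_s, overlap_s = overlap_s,
                 n_segments = ws$n_segments, db = FALSE),
            class = "psd_spectrum")
}

#' @export
print.psd_spectrum <- function(x, ...) {
  cat(sprintf("psd_spectrum: %d bins %.3g-%.4g Hz (%d segments)%s\n",
              length(x$freqs), min(x$freqs), max(x$freqs), x$n_segments,
              if (x$db) " [dB]" else ""))
  invisible(x)
}

#' Band power of a PSD (trapezoidal integral)
#'
#' Integrates the density over frequencies in `[low, high]`, so a flat PSD
#' of height 1 over an 8-12 Hz band yields 4.
#'
#' @param psd a `psd_spectrum` (linear units, not dB).
#' @param band `c(low, high)` in Hz.
#' @return scalar power (units^2).
#' @export
band_power <- function(psd, band) {
  if (isTRUE(psd$db)) stop("band_power expects a linear-scale PSD")
  sel <- psd$freqs >= band[1] & psd$freqs <= band[2]
  if (sum(sel) < 2) stop("band [", band[1], ", ", band[2],
                         ") does not intersect the PSD frequency grid")
  f <- psd$freqs[sel]; p <- psd$power[sel]
  sum(diff(f) * (head(p, -1) + p[-1]) / 2)
}

#' Decibel transform of a PSD
#'
#' @param psd a linear-scale `psd_spectrum`.
#' @return the same spectrum with `power` mapped to `10*log10(power)`.
#' @export
to_db <- function(psd) {
  if (isTRUE(psd$db)) stop("PSD is already in dB")
  psd$power <- 10 * log10(psd$power)
  psd$db <- TRUE
  psd
}

# ---- thin-plate-spline RBF interpolation of the electrode grid ----

tps_kernel <- function(r) ifelse(r == 0, 0, r^2 * log(r))

tps_fit <- function(xy, v) {
  n <- nrow(xy)
  K <- tps_kernel(as.matrix(stats::dist(xy)))
  P <- cbind(1, xy)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  sol <- solve(A, c(v, numeric(3)))
  list(w = sol[1:n], c = sol[n + 1:3], centers = xy)
}

tps_eval <- function(fit, xy) {
  d <- sqrt(outer(xy[, 1], fit$centers[, 1], "-")^2 +
            outer(xy[, 2], fit$centers[, 2], "-")^2)
  as.vector(tps_kernel(d) %*% fit$w + cbind(1, xy) %*% fit$c)
}

#' Interpolate per-electrode band power over the grid
#'
#' Thin-plate-spline radial basis interpolation (with a linear polynomial
#' tail, hence exact at the nodes and constant-preserving) of the 8x8
#' electrode power map onto an `out_size x out_size` grid spanning the
#' array extent.
#'
#' @param values named numeric vector of per-channel power (names are
#'   channel ids present in the layout).
#' @param layout an [electrode_layout()].
#' @param out_size output grid edge length (default 100).
#' @param band optional `c(low, high)` Hz annotation.
#' @return a `spatial_power_map`: list with `raw` (n_rows x n_cols, NA at
#'   unused sites), `interpolated` (out_size x out_size), `band`, and
#'   `node_values` (the interpolant evaluated back at the node positions).
#' @export
spatial_map <- function(values, layout, out_size = 100, band = NULL) {
  coords <- layout_coords(layout)
  miss <- setdiff(coords$channel_id, names(values))
  if (length(miss))
    stop("missing power values for channel(s): ", paste(miss, collapse = ", "))
  v <- as.numeric(values[coords$channel_id])
  xy <- cbind(coords$row, coords$col)
  if (nrow(xy) < 3 || qr(cbind(1, xy))$rank < 3)
    stop("need at least 3 non-collinear electrode positions")
  fit <- tps_fit(xy, v)
  gr <- seq(1, layout$n_rows, length.out = out_size)
  gc <- seq(1, layout$n_cols, length.out = out_size)
  grid <- cbind(rep(gr, times = out_size), rep(gc, each = out_size))
  interp <- matrix(tps_eval(fit, grid), out_size, out_size)
  raw <- matrix(NA_real_, layout$n_rows, layout$n_cols)
  raw[cbind(coords$row, coords$col)] <- v
  structure(list(raw = raw, interpolated = interp, band = band,
                 node_values = tps_eval(fit, xy), values = v,
                 coords = coords),
            class = "spatial_power_map")
}

#' Extract a fixed-length segment at a Zeitgeber time
#'
#' ZT0 is lights-on; the segment starts at `zt_start` hours after the
#' session origin (assumed lights-on unless `lights_on_s` says otherwise).
#'
#' @param rec an [recording()].
#' @param zt_start start time in ZT hours; `length_s` segment length
#'   (default 15 s, the standard analysis segment).
#' @param lights_on_s session time of lights-on in seconds.
#' @return an [recording()] covering the segment.
#' @export
select_segment <- function(rec, zt_start, length_s = 15, lights_on_s = 0) {
  t0 <- lights_on_s + zt_start * 3600 - rec$start_time
  t1 <- t0 + length_s
  span <- ncol(rec$samples) / rec$fs
  if (t0 < 0 || t1 > span)
    stop(sprintf("segment [%.1f, %.1f) s outside recording span [0, %.1f) s",
                 t0, t1, span))
  i0 <- floor(t0 * rec$fs) + 1
  i1 <- i0 + round(length_s * rec$fs) - 1
  recording(rec$samples[, i0:i1, drop = FALSE], fs = rec$fs,
            channel_ids = rec$channel_ids, layout = rec$layout,
            start_time = rec$start_time + t0)
}

#' @importFrom utils head
NULL
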