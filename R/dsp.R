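# Core signal-processing primitives: IIR design (Butterworth via bilinear
# transform, second-order sections), zero-phase filtering, notch biquads,
# Hilbert analytic signal, Welch auto/cross spectra, polyphase resampling,
# and FastICA. All frequencies at the user surface are in Hz; internal
# design routines use frequencies normalized to the Nyquist rate (0..1).

#' @useDynLib ecogsleep, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft mvfft nextn rnorm runif sd mad approx median
NULL

# ---- Butterworth design (zpk -> bilinear -> second-order sections) ----

butter_prototype <- function(order) {
  k <- seq_len(order)
  exp(1i * pi * (2 * k + order - 1) / (2 * order))  # left-half-plane poles
}

# zpk in the analog domain for the requested band transform.
# w: normalized edge(s) in (0, 1), Nyquist = 1.
butter_zpk_analog <- function(order, w, type) {
  p <- butter_prototype(order)
  z <- complex(0)
  k <- 1  # Butterworth prototype: prod(-p) == 1
  fs2 <- 2
  warped <- 2 * fs2 * tan(pi * w / fs2)
  if (type == "low") {
    w0 <- warped[1]
    p <- p * w0
    k <- w0^order
  } else if (type == "high") {
    w0 <- warped[1]
    p <- w0 / p
    z <- rep(0 + 0i, order)
    # k * prod(-z_proto)/prod(-p_proto) = k for Butterworth
  } else if (type == "pass") {
    bw <- warped[2] - warped[1]
    w0 <- sqrt(warped[1] * warped[2])
    ph <- p * bw / 2
    disc <- sqrt(ph^2 - w0^2)
    p <- c(ph + disc, ph - disc)
    z <- rep(0 + 0i, order)
    k <- bw^order
  } else if (type == "stop") {
    bw <- warped[2] - warped[1]
    w0 <- sqrt(warped[1] * warped[2])
    ph <- (bw / 2) / p
    disc <- sqrt(ph^2 - w0^2)
    p <- c(ph + disc, ph - disc)
    z <- rep(c(1i * w0, -1i * w0), order)
  } else {
    stop("unknown filter type: ", type)
  }
  list(z = z, p = p, k = k)
}

bilinear_zpk <- function(zpk, fs2 = 2) {
  z <- zpk$z; p <- zpk$p; k <- zpk$k
  deg <- length(p) - length(z)
  zd <- (1 + z / (2 * fs2)) / (1 - z / (2 * fs2))
  pd <- (1 + p / (2 * fs2)) / (1 - p / (2 * fs2))
  kd <- k * Re(prod(2 * fs2 - z) / prod(2 * fs2 - p))
  zd <- c(zd, rep(-1 + 0i, deg))
  list(z = zd, p = pd, k = kd)
}

# Group a root multiset into conjugate pairs (plus real pairs / singletons).
pair_conjugates <- function(v, tol = 1e-7) {
  pairs <- list()
  singles <- list()
  v <- v[order(-abs(v))]
  used <- rep(FALSE, length(v))
  for (i in seq_along(v)) {
    if (used[i]) next
    used[i] <- TRUE
    if (abs(Im(v[i])) < tol * max(1, abs(v[i]))) {
      # real root: pair with another unused real root if available
      j <- which(!used & abs(Im(v)) < tol * pmax(1, abs(v)))
      if (length(j)) {
        j <- j[which.min(abs(Re(v[j]) - Re(v[i])))]
        used[j] <- TRUE
        pairs[[length(pairs) + 1]] <- c(v[i], v[j])
      } else {
        singles[[length(singles) + 1]] <- v[i]
      }
    } else {
      j <- which(!used)
      j <- j[which.min(abs(v[j] - Conj(v[i])))]
      used[j] <- TRUE
      pairs[[length(pairs) + 1]] <- c(v[i], v[j])
    }
  }
  list(pairs = pairs, singles = singles)
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  Re(p)
}

# Convert digital zpk to an n x 6 second-order-section matrix.
zpk2sos <- function(zpk) {
  z <- zpk$z; p <- zpk$p; k <- zpk$k
  stopifnot(length(z) == length(p))
  if (!length(p)) return(matrix(c(k, 0, 0, 1, 0, 0), 1))
  pp <- pair_conjugates(p)
  zz <- pair_conjugates(z)
  if (length(pp$singles) != length(zz$singles))
    stop("unbalanced first-order remainder in zpk2sos")
  sections <- list()
  zpairs <- zz$pairs
  for (pe in pp$pairs) {
    if (length(zpairs)) {
      d <- vapply(zpairs, function(ze) min(Mod(outer(ze, pe, "-"))), 0)
      j <- which.min(d)
      ze <- zpairs[[j]]
      zpairs[[j]] <- NULL
    } else ze <- complex(0)
    b <- poly_from_roots(ze)
    a <- poly_from_roots(pe)
    b <- c(b, rep(0, 3 - length(b)))
    sections[[length(sections) + 1]] <- c(b, a)
  }
  for (i in seq_along(pp$singles)) {
    b <- poly_from_roots(zz$singles[[i]])
    a <- poly_from_roots(pp$singles[[i]])
    sections[[length(sections) + 1]] <- c(b, 0, a, 0)
  }
  sos <- do.call(rbind, sections)
  # sections with poles nearest the unit circle last; gain on the first
  ord <- order(vapply(seq_len(nrow(sos)), function(i) {
    r <- polyroot(rev(sos[i, 4:6]))
    if (length(r)) max(Mod(r)) else 0
  }, 0))
  sos <- sos[ord, , drop = FALSE]
  sos[1, 1:3] <- sos[1, 1:3] * k
  sos
}

#' Design a digital Butterworth filter as second-order sections
#'
#' @param order filter order of the analog prototype.
#' @param w critical frequency (Hz): scalar for `"low"`/`"high"`, length-2
#'   `c(low, high)` for `"pass"`/`"stop"`.
#' @param fs sampling rate in Hz.
#' @param type one of `"low"`, `"high"`, `"pass"`, `"stop"`.
#' @return numeric matrix with one row per biquad section, columns
#'   `b0 b1 b2 a0 a1 a2` (`a0 = 1`).
#' @export
butter_design <- function(order, w, fs, type = c("low", "high", "pass", "stop")) {
  type <- match.arg(type)
  wn <- w / (fs / 2)
  if (any(wn <= 0) || any(wn >= 1))
    stop("critical frequencies must lie strictly inside (0, Nyquist)")
  if (type %in% c("pass", "stop") && length(wn) != 2)
    stop("band filters need two edge frequencies")
  zpk2sos(bilinear_zpk(butter_zpk_analog(order, wn, type)))
}

# Second-order IIR notch (RBJ/scipy iirnotch form).
notch_design <- function(f0, fs, q = 30) {
  if (f0 >= fs / 2) stop("notch frequency ", f0, " Hz is at or above Nyquist (fs = ", fs, ")")
  w0 <- pi * f0 / (fs / 2)
  beta <- tan(w0 / (2 * q))
  gain <- 1 / (1 + beta)
  matrix(c(gain, -2 * gain * cos(w0), gain,
           1, -2 * gain * cos(w0), 2 * gain - 1), 1)
}

# Steady-state initial conditions per section (transposed direct form II),
# scaled downstream by the cumulative DC gain of preceding sections.
sosfilt_zi <- function(sos) {
  ns <- nrow(sos)
  zi <- matrix(0, ns, 2)
  scale <- 1
  for (s in seq_len(ns)) {
    b <- sos[s, 1:3]; a <- sos[s, 4:6]
    A <- rbind(c(-a[2], 1), c(-a[3], 0))
    B <- c(b[2] - b[1] * a[2], b[3] - b[1] * a[3])
    zi[s, ] <- scale * solve(diag(2) - A, B)
    scale <- scale * sum(b) / sum(a)
  }
  zi
}

sosfilt <- function(sos, x, zi = NULL) {
  if (is.null(zi)) zi <- matrix(0, nrow(sos), 2)
  y <- .sosfilt_cpp(sos, as.numeric(x), zi)
  attr(y, "zf") <- NULL
  y
}

#' Zero-phase (forward-backward) filtering with second-order sections
#'
#' Applies the filter forward and backward with odd-reflection edge padding
#' and steady-state initial conditions, so the output has no group delay.
#'
#' @param sos section matrix from [butter_design()] or a notch design.
#' @param x numeric signal.
#' @param padlen samples of edge padding; default grows with section count.
#' @export
sos_filtfilt <- function(sos, x, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) padlen <- 3 * (2 * nrow(sos) + 1)
  padlen <- min(padlen, n - 1)
  if (padlen < 1) stop("signal too short to filter")
  ext <- c(2 * x[1] - x[(padlen + 1):2],
           x,
           2 * x[n] - x[(n - 1):(n - padlen)])
  zi <- sosfilt_zi(sos)
  y <- sosfilt(sos, ext, zi * ext[1])
  y <- rev(y)
  y <- sosfilt(sos, y, zi * y[1])
  y <- rev(y)
  y[(padlen + 1):(padlen + n)]
}

sos_freq_response <- function(sos, f, fs) {
  w <- 2 * pi * f / fs
  ez <- exp(-1i * w)
  h <- rep(1 + 0i, length(w))
  for (s in seq_len(nrow(sos))) {
    num <- sos[s, 1] + sos[s, 2] * ez + sos[s, 3] * ez^2
    den <- sos[s, 4] + sos[s, 5] * ez + sos[s, 6] * ez^2
    h <- h * num / den
  }
  h
}

# ---- Hilbert analytic signal ----

#' Analytic signal via the FFT Hilbert transform
#'
#' @param x real signal.
#' @return complex vector; `Mod()` of it is the instantaneous envelope.
#' @export
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# ---- Welch auto- and cross-spectra ----

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / n - 2 * pi / n)

segment_matrix <- function(x, nper, step) {
  n <- length(x)
  starts <- seq(1, n - nper + 1, by = step)
  vapply(starts, function(s) x[s:(s + nper - 1)], numeric(nper))
}

# One-sided Welch spectra for one or two signals. Returns density-scaled
# Pxx (and Pyy, Pxy when y is given); averages modified periodograms of
# Hann-windowed, per-segment demeaned segments.
welch_spectra <- function(x, y = NULL, fs, window_s = 2, overlap_s = window_s / 2) {
  nper <- round(window_s * fs)
  nover <- round(overlap_s * fs)
  if (nover >= nper) stop("overlap must be shorter than the window")
  if (length(x) < nper) stop("signal shorter than one window (", window_s, " s)")
  step <- nper - nover
  w <- hann_window(nper)
  scale <- 1 / (fs * sum(w^2))
  segX <- segment_matrix(x, nper, step)
  segX <- (segX - rep(colMeans(segX), each = nper)) * w
  FX <- mvfft(segX)
  nfreq <- nper %/% 2 + 1
  FX <- FX[1:nfreq, , drop = FALSE]
  dbl <- rep(2, nfreq); dbl[1] <- 1
  if (nper %% 2 == 0) dbl[nfreq] <- 1
  pxx <- rowMeans(Mod(FX)^2) * scale * dbl
  freqs <- (0:(nfreq - 1)) * fs / nper
  out <- list(freqs = freqs, pxx = pxx, n_segments = ncol(segX))
  if (!is.null(y)) {
    if (length(y) != length(x)) stop("x and y must have equal length")
    segY <- segment_matrix(y, nper, step)
    segY <- (segY - rep(colMeans(segY), each = nper)) * w
    FY <- mvfft(segY)[1:nfreq, , drop = FALSE]
    out$pyy <- rowMeans(Mod(FY)^2) * scale * dbl
    out$pxy <- rowMeans(Conj(FX) * FY) * scale * dbl
  }
  out
}

# ---- Polyphase resampling ----

kaiser_window <- function(n, beta) {
  m <- n - 1
  x <- (0:m - m / 2) / (m / 2)
  besselI(beta * sqrt(pmax(0, 1 - x^2)), 0) / besselI(beta, 0)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Rational-rate resampling with a Kaiser-windowed sinc anti-aliasing filter.
resample_rational <- function(x, up, down) {
  g <- gcd_int(up, down)
  up <- up %/% g; down <- down %/% g
  if (up == 1 && down == 1) return(x)
  max_rate <- max(up, down)
  half_len <- as.integer(down * ceiling(10 * max_rate / down))
  m <- 2L * half_len + 1L
  fc <- 1 / max_rate  # relative to the upsampled Nyquist
  n0 <- (0:(m - 1)) - half_len
  h <- fc * sinc(fc * n0) * kaiser_window(m, 5.0) * up
  yfull <- .upfirdn_cpp(h, as.numeric(x), as.integer(up), as.integer(down))
  start <- half_len %/% down
  n_out <- ceiling(length(x) * up / down)
  yfull[start + seq_len(n_out)]
}

gcd_int <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

# ---- FastICA ----

#' FastICA decomposition (symmetric, logcosh contrast)
#'
#' Whitens the channel-by-time matrix to `n_components` principal directions
#' and runs symmetric fixed-point FastICA. Deterministic for a fixed RNG
#' state (the random orthonormal start is drawn from the current RNG).
#'
#' @param x channels x samples numeric matrix.
#' @param n_components number of components to extract (default 32).
#' @param max_iter,tol fixed-point iteration controls.
#' @return list with `sources` (components x samples), `mixing`
#'   (channels x components), `unmixing` (components x channels), such that
#'   `mixing %*% sources` reconstructs the retained principal subspace of
#'   the centered input.
#' @export
fast_ica <- function(x, n_components = 32, max_iter = 400, tol = 1e-6) {
  if (!is.matrix(x)) stop("x must be a channels x samples matrix")
  nch <- nrow(x); n <- ncol(x)
  if (n_components > nch) stop("more components than channels")
  if (n <= 2 * nch) stop("too few samples for a stable decomposition")
  mu <- rowMeans(x)
  xc <- x - mu
  cv <- tcrossprod(xc) / n
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[n_components] < 1e-12 * eg$values[1])
    stop("rank-deficient input: fewer than n_components independent directions")
  K <- t(eg$vectors[, 1:n_components, drop = FALSE]) / sqrt(eg$values[1:n_components])
  z <- K %*% xc  # whitened: cov(z) = I
  w0 <- matrix(rnorm(n_components^2), n_components)
  W <- sym_decorrelate(w0)
  for (it in seq_len(max_iter)) {
    wz <- W %*% z
    g <- tanh(wz)
    gp <- rowMeans(1 - g^2)
    Wn <- g %*% t(z) / n - gp * W
    Wn <- sym_decorrelate(Wn)
    delta <- max(abs(abs(rowSums(Wn * W)) - 1))
    W <- Wn
    if (delta < tol) break
  }
  unmixing <- W %*% K
  mixing <- eg$vectors[, 1:n_components, drop = FALSE] %*%
    (sqrt(eg$values[1:n_components]) * t(W))
  list(sources = unmixing %*% xc, mixing = mixing, unmixing = unmixing,
       center = mu, n_iter = it)
}

sym_decorrelate <- function(W) {
  s <- eigen(W %*% t(W), symmetric = TRUE)
  s$vectors %*% (t(s$vectors) / sqrt(s$values)) %*% W
}
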