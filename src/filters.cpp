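#include <Rcpp.h>
using namespace Rcpp;

// Cascade of biquads in transposed direct form II.
// sos: n_sections x 6 matrix (b0 b1 b2 a0 a1 a2), a0 == 1.
// zi: n_sections x 2 initial state (modified in a copy; final state returned
// via attribute so filtfilt can chain passes if ever needed).
// [[Rcpp::export(name = ".sosfilt_cpp")]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x, NumericMatrix zi) {
  const int ns = sos.nrow();
  const R_xlen_t n = x.size();
  NumericVector y = clone(x);
  NumericMatrix z = clone(zi);
  for (int s = 0; s < ns; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 4), a2 = sos(s, 5);
    double z1 = z(s, 0), z2 = z(s, 1);
    for (R_xlen_t i = 0; i < n; ++i) {
      const double xi = y[i];
      const double yi = b0 * xi + z1;
      z1 = b1 * xi - a1 * yi + z2;
      z2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
    z(s, 0) = z1;
    z(s, 1) = z2;
  }
  y.attr("zf") = z;
  return y;
}

// Polyphase-style FIR resampling: upsample by `up`, filter with `h`,
// downsample by `down`. Computes only the kept output samples.
// [[Rcpp::export(name = ".upfirdn_cpp")]]
NumericVector upfirdn_cpp(NumericVector h, NumericVector x, int up, int down) {
  const R_xlen_t nx = x.size(), nh = h.size();
  // length of full convolution on the upsampled grid, then strided by `down`
  const R_xlen_t nfull = (nx - 1) * up + nh;
  const R_xlen_t nout = (nfull + down - 1) / down;
  NumericVector y(nout);
  for (R_xlen_t k = 0; k < nout; ++k) {
    const R_xlen_t t = k * down;  // index on upsampled grid
    // y[t] = sum_j h[j] * xup[t - j], xup nonzero at multiples of up
    R_xlen_t jmin = t - (nx - 1) * up;
    if (jmin < 0) jmin = 0;
    // smallest j >= jmin with (t - j) % up == 0
    R_xlen_t r = (t - jmin) % up;
    R_xlen_t j = jmin + r;
    double acc = 0.0;
    for (; j < nh && j <= t; j += up) {
      acc += h[j] * x[(t - j) / up];
    }
    y[k] = acc;
  }
  return y;
}
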