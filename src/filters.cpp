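#include <Rcpp.h>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter with initial conditions.
// Coefficients must be normalised (a[0] == 1) and padded to equal length.
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  const int n = x.size();
  const int nf = b.size();
  NumericVector y(n);
  std::vector<double> z(zi.begin(), zi.end());  // length nf - 1
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + z[0];
    for (int j = 1; j < nf - 1; ++j) {
      z[j - 1] = b[j] * xi + z[j] - a[j] * yi;
    }
    z[nf - 2] = b[nf - 1] * xi - a[nf - 1] * yi;
    y[i] = yi;
  }
  return y;
}

// Forward-backward (zero-phase) filter over an already-padded signal:
// the backward pass runs in place on the forward output, avoiding the two
// explicit reversals. zi holds the steady-state unit-step state; it is
// scaled by the first processed sample of each pass.
static inline void df2t_pass(const double *bp, const double *ap, int nf,
                             const double *in, double *out,
                             R_xlen_t n, R_xlen_t step, double *z) {
  const R_xlen_t start = step > 0 ? 0 : n - 1;
  for (R_xlen_t k = 0, i = start; k < n; ++k, i += step) {
    const double xi = in[i];
    const double yi = bp[0] * xi + z[0];
    for (int j = 1; j < nf - 1; ++j) {
      z[j - 1] = bp[j] * xi + z[j] - ap[j] * yi;
    }
    z[nf - 2] = bp[nf - 1] * xi - ap[nf - 1] * yi;
    out[i] = yi;
  }
}

// NOTE: filters in place — `ext` is overwritten with the result. Callers
// always pass a freshly built padded buffer.
// [[Rcpp::export]]
NumericVector filtfilt_cpp(NumericVector b, NumericVector a,
                           NumericVector ext, NumericVector zi) {
  const R_xlen_t n = ext.size();
  const int nf = b.size();
  std::vector<double> bp(b.begin(), b.end());
  std::vector<double> ap(a.begin(), a.end());
  std::vector<double> z(nf - 1);
  double *xp = ext.begin();
  for (int j = 0; j < nf - 1; ++j) z[j] = zi[j] * xp[0];
  df2t_pass(bp.data(), ap.data(), nf, xp, xp, n, 1, z.data());
  for (int j = 0; j < nf - 1; ++j) z[j] = zi[j] * xp[n - 1];
  df2t_pass(bp.data(), ap.data(), nf, xp, xp, n, -1, z.data());
  return ext;
}

// Vector magnitude of the three axes written directly into a buffer with
// odd-reflection padding of nfact samples at each end, ready for
// zero-phase filtering without further copies.
// [[Rcpp::export]]
NumericVector vm3_padded_cpp(NumericVector ax, NumericVector ay,
                             NumericVector az, int nfact) {
  const R_xlen_t n = ax.size();
  NumericVector out(n + 2 * (R_xlen_t)nfact);
  double *op = out.begin() + nfact;
  for (R_xlen_t i = 0; i < n; ++i) {
    op[i] = std::sqrt(ax[i] * ax[i] + ay[i] * ay[i] + az[i] * az[i]);
  }
  for (int k = 1; k <= nfact; ++k) {
    op[-k] = 2.0 * op[0] - op[k];
    op[n - 1 + k] = 2.0 * op[n - 1] - op[n - 1 - k];
  }
  return out;
}

// Euclidean norm of the three acceleration axes in one pass.
// [[Rcpp::export]]
NumericVector vm3_cpp(NumericVector ax, NumericVector ay, NumericVector az) {
  const R_xlen_t n = ax.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = std::sqrt(ax[i] * ax[i] + ay[i] * ay[i] + az[i] * az[i]);
  }
  return out;
}

// Population SD (denominator n) over non-overlapping windows of m samples;
// the trailing partial window is dropped.
// [[Rcpp::export]]
NumericVector windowed_sd_cpp(NumericVector x, int m) {
  const R_xlen_t k = x.size() / m;
  NumericVector out(k);
  for (R_xlen_t w = 0; w < k; ++w) {
    double s = 0.0, s2 = 0.0;
    const R_xlen_t off = w * m;
    for (int i = 0; i < m; ++i) {
      const double v = x[off + i];
      s += v;
      s2 += v * v;
    }
    const double mu = s / m;
    const double var = s2 / m - mu * mu;
    out[w] = var > 0 ? std::sqrt(var) : 0.0;
  }
  return out;
}

// In place: x[i] <- x[i] * lev[i / per] + g(i), where g is piecewise
// constant over segments starting at seg_starts (1-based) with values
// gvals. Used to turn unit white noise into the simulated axis signal
// without materialising the expanded level vector.
// [[Rcpp::export]]
NumericVector scale_noise_cpp(NumericVector x, NumericVector lev, int per,
                              NumericVector gvals, IntegerVector seg_starts) {
  const R_xlen_t n = x.size();
  const R_xlen_t nlev = lev.size();
  int seg = 0;
  const int nseg = seg_starts.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    while (seg + 1 < nseg && i + 1 >= seg_starts[seg + 1]) ++seg;
    R_xlen_t li = i / per;
    if (li >= nlev) li = nlev - 1;
    x[i] = x[i] * lev[li] + gvals[seg];
  }
  return x;
}
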