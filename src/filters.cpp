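#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR pass over a raw buffer, in place.
// order-4 fast path: filter state kept in registers
static void df2t_pass4(const double* b, const double* a,
                       double* x, int n, bool reverse) {
  const double b0 = b[0], b1 = b[1], b2 = b[2], b3 = b[3], b4 = b[4];
  const double a1 = a[1], a2 = a[2], a3 = a[3], a4 = a[4];
  double w0 = 0.0, w1 = 0.0, w2 = 0.0, w3 = 0.0;
  int i0 = reverse ? n - 1 : 0;
  int step = reverse ? -1 : 1;
  for (int k = 0; k < n; ++k) {
    int i = i0 + step * k;
    double xi = x[i];
    double yi = b0 * xi + w0;
    w0 = b1 * xi - a1 * yi + w1;
    w1 = b2 * xi - a2 * yi + w2;
    w2 = b3 * xi - a3 * yi + w3;
    w3 = b4 * xi - a4 * yi;
    x[i] = yi;
  }
}

static void df2t_pass(const std::vector<double>& b,
                      const std::vector<double>& a,
                      double* x, int n, bool reverse) {
  const int nw = (int) b.size();   // b and a padded to equal length
  if (nw == 5) {
    df2t_pass4(b.data(), a.data(), x, n, reverse);
    return;
  }
  std::vector<double> w(nw, 0.0);
  int i0 = reverse ? n - 1 : 0;
  int step = reverse ? -1 : 1;
  for (int k = 0; k < n; ++k) {
    int i = i0 + step * k;
    double xi = x[i];
    double yi = b[0] * xi + w[0];
    for (int j = 0; j < nw - 1; ++j)
      w[j] = b[j + 1] * xi - a[j + 1] * yi + w[j + 1];
    w[nw - 2] = b[nw - 1] * xi - a[nw - 1] * yi;
    x[i] = yi;
  }
}

static void norm_coeffs(NumericVector b, NumericVector a,
                        std::vector<double>& bb, std::vector<double>& aa) {
  int nb = b.size(), na = a.size();
  if (na < 1 || a[0] == 0.0) stop("invalid denominator coefficients");
  int nw = std::max(nb, na);
  if (nw < 2) stop("filter must have order >= 1");
  bb.assign(nw, 0.0); aa.assign(nw, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a[0];
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a[0];
}

// Single-pass IIR filter, y = filter(b, a, x), zero initial state.
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x) {
  std::vector<double> bb, aa;
  norm_coeffs(b, a, bb, aa);
  NumericVector y = clone(x);
  df2t_pass(bb, aa, REAL(y), y.size(), false);
  return y;
}

// Zero-phase filter: odd-reflection padding of `pad` samples at both ends,
// forward pass, reverse pass, pads dropped.
// [[Rcpp::export]]
NumericVector zero_phase_filter_cpp(NumericVector b, NumericVector a,
                                    NumericVector x, int pad) {
  std::vector<double> bb, aa;
  norm_coeffs(b, a, bb, aa);
  int n = x.size();
  if (pad < 0 || n <= pad) stop("series too short for zero-phase filtering");
  std::vector<double> buf(n + 2 * pad);
  const double* px = REAL(x);
  for (int i = 0; i < pad; ++i) buf[i] = 2.0 * px[0] - px[pad - i];
  std::copy(px, px + n, buf.begin() + pad);
  for (int i = 0; i < pad; ++i)
    buf[pad + n + i] = 2.0 * px[n - 1] - px[n - 2 - i];
  df2t_pass(bb, aa, buf.data(), (int) buf.size(), false);
  df2t_pass(bb, aa, buf.data(), (int) buf.size(), true);
  NumericVector y(n);
  std::copy(buf.begin() + pad, buf.begin() + pad + n, REAL(y));
  return y;
}
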