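#include <Rcpp.h>
using namespace Rcpp;

// Classical Lomb normalized-least-squares periodogram on an equally spaced
// frequency grid f_k = f0 + k * df (Hz), k = 0..nf-1, for samples y at
// times t (seconds). Values are centered by the caller. A rotation
// recurrence over the grid evaluates trig functions only once per sample;
// the cosine/sine tables from the tau pass are cached (nf * n doubles,
// ~30 MB at the package's largest grids) and both passes run with the
// frequency index innermost so all accesses are contiguous.
// [[Rcpp::export]]
NumericVector lomb_power_cpp(NumericVector t, NumericVector y,
                             double f0, double df, int nf) {
  const int n = t.size();
  const double two_pi = 2.0 * M_PI;
  std::vector<double> S2(nf, 0.0), C2(nf, 0.0);
  std::vector<double> ct(static_cast<size_t>(n) * nf), st(static_cast<size_t>(n) * nf);

  // pass 1: sums of sin/cos(2 w t) defining the tau offset
  for (int j = 0; j < n; ++j) {
    const double a = std::cos(two_pi * df * t[j]);
    const double b = std::sin(two_pi * df * t[j]);
    double c = std::cos(two_pi * f0 * t[j]);
    double s = std::sin(two_pi * f0 * t[j]);
    double *cj = &ct[static_cast<size_t>(j) * nf];
    double *sj = &st[static_cast<size_t>(j) * nf];
    for (int k = 0; k < nf; ++k) {
      S2[k] += 2.0 * s * c;        // sin(2 w t)
      C2[k] += c * c - s * s;      // cos(2 w t)
      cj[k] = c;
      sj[k] = s;
      const double cn = c * a - s * b;
      s = s * a + c * b;
      c = cn;
    }
  }

  std::vector<double> cw(nf), sw(nf);
  for (int k = 0; k < nf; ++k) {
    const double wtau = 0.5 * std::atan2(S2[k], C2[k]); // angle w * tau
    cw[k] = std::cos(wtau);
    sw[k] = std::sin(wtau);
  }

  // pass 2: projections onto cos/sin(w (t - tau)) from the cached tables
  std::vector<double> yc(nf, 0.0), ys(nf, 0.0), cc(nf, 0.0), ss(nf, 0.0);
  for (int j = 0; j < n; ++j) {
    const double yj = y[j];
    const double *cjt = &ct[static_cast<size_t>(j) * nf];
    const double *sjt = &st[static_cast<size_t>(j) * nf];
    for (int k = 0; k < nf; ++k) {
      const double cj = cjt[k] * cw[k] + sjt[k] * sw[k];
      const double sj = sjt[k] * cw[k] - cjt[k] * sw[k];
      yc[k] += yj * cj;
      ys[k] += yj * sj;
      cc[k] += cj * cj;
      ss[k] += sj * sj;
    }
  }

  NumericVector p(nf);
  for (int k = 0; k < nf; ++k) {
    double val = 0.0;
    if (cc[k] > 1e-12) val += yc[k] * yc[k] / cc[k];
    if (ss[k] > 1e-12) val += ys[k] * ys[k] / ss[k];
    p[k] = 0.5 * val;
  }
  return p;
}
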