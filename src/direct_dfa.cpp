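#include <Rcpp.h>
using namespace Rcpp;

// Kahan-compensated accumulator
struct KSum {
  double s = 0.0, c = 0.0;
  inline void add(double x) {
    double t = x - c;
    double u = s + t;
    c = (u - s) - t;
    s = u;
  }
};

// Direct per-block residual variances: moments summed sample by sample in
// the local index j = 1..n (compensated), analytic normal-equation solve,
// residual sum of squares taken directly. This is the slow reference path;
// it is also used to recompute blocks whose fast analytic variance falls
// below the precision threshold.
// [[Rcpp::export]]
NumericVector direct_variances_cpp(NumericVector y, IntegerVector starts,
                                   int n, int order) {
  const int M = starts.size();
  const int N = y.size();
  if (order != 1 && order != 2) stop("order must be 1 or 2");
  if (n < order + 2) stop("degenerate fit: need n >= order + 2");
  NumericVector out(M);

  const double nn = (double)n;
  const double P1 = nn * (nn + 1.0) / 2.0;
  const double P2 = nn * (nn + 1.0) * (2.0 * nn + 1.0) / 6.0;
  const double P3 = P1 * P1;
  const double P4 = nn * (nn + 1.0) * (2.0 * nn + 1.0) *
                    (3.0 * nn * nn + 3.0 * nn - 1.0) / 30.0;
  const double mj = (nn + 1.0) / 2.0;
  const double mj2 = P2 / nn;
  const double Sii = mj2 - mj * mj;
  const double Sii2 = P3 / nn - mj * mj2;
  const double Si2i2 = P4 / nn - mj2 * mj2;

  for (int k = 0; k < M; ++k) {
    const int I = starts[k];
    if (I < 1 || I + n - 1 > N) stop("block outside series");
    const double *z = &y[I - 1];
    KSum s0, s1, s2;
    for (int j = 1; j <= n; ++j) {
      const double zz = z[j - 1];
      s0.add(zz);
      s1.add((double)j * zz);
      if (order == 2) s2.add((double)j * (double)j * zz);
    }
    const double ybar = s0.s / nn;
    const double Siy = s1.s / nn - mj * ybar;
    double a, b, c2 = 0.0;
    if (order == 1) {
      b = Siy / Sii;
      a = ybar - b * mj;
    } else {
      const double Si2y = s2.s / nn - mj2 * ybar;
      const double den = Sii * Si2i2 - Sii2 * Sii2;
      c2 = (Si2y * Sii - Siy * Sii2) / den;
      b = (Siy * Si2i2 - Si2y * Sii2) / den;
      a = ybar - b * mj - c2 * mj2;
    }
    KSum rss;
    for (int j = 1; j <= n; ++j) {
      const double jj = (double)j;
      const double r = z[j - 1] - (a + b * jj + c2 * jj * jj);
      rss.add(r * r);
    }
    out[k] = rss.s / nn;
  }
  return out;
}
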