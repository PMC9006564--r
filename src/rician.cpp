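#include <Rcpp.h>
#include <Rmath.h>
#include <cmath>
using namespace Rcpp;

// log I0(x) for x >= 0 via the Abramowitz-Stegun 9.8.1/9.8.2 rational
// approximations (|error| < 2e-7), much faster than the library Bessel.
static inline double log_i0(double x) {
  if (x < 3.75) {
    double t = x / 3.75, t2 = t * t;
    double p = 1.0 + t2 * (3.5156229 + t2 * (3.0899424 + t2 * (1.2067492
               + t2 * (0.2659732 + t2 * (0.0360768 + t2 * 0.0045813)))));
    return std::log(p);
  }
  double t = 3.75 / x;
  double p = 0.39894228 + t * (0.01328592 + t * (0.00225319 + t * (-0.00157565
             + t * (0.00916281 + t * (-0.02057706 + t * (0.02635537
             + t * (-0.01647633 + t * 0.00392377)))))));
  return x + std::log(p) - 0.5 * std::log(x);
}

// Rician log-likelihood of samples x at (s, sigma), dropping the
// parameter-free sum(log x) term; even in s, so the optimizer roams over
// the real line and |s| is reported.
// log f(x) = log I0(x*s/sig2) + log x - log sig2 - (x^2 + s^2)/(2 sig2)
static double rician_loglik(const std::vector<double>& x, double s, double sigma) {
  if (sigma <= 0.0) return -INFINITY;
  const double sig2 = sigma * sigma;
  const double sa = std::fabs(s);
  const int n = (int)x.size();
  double sum_li0 = 0.0, sum_x2 = 0.0;
  const double a = sa / sig2;
  for (double xi : x) { sum_li0 += log_i0(xi * a); sum_x2 += xi * xi; }
  return sum_li0 - n * std::log(sig2) - (sum_x2 + n * s * s) / (2.0 * sig2);
}

// parameter-free part of the log-likelihood, added once after optimization
static double loglik_const(const std::vector<double>& x) {
  double s = 0.0;
  for (double xi : x) s += std::log(xi);
  return s;
}

// Compact Nelder-Mead on (s, log sigma), 2 parameters.
static void nelder_mead(const std::vector<double>& x, double& s, double& sigma,
                        double& ll, bool& ok) {
  const int maxit = 300;
  const double tol = 1e-8;
  double p[3][2] = {{s, std::log(sigma)},
                    {s + 0.1 * sigma + 1e-3, std::log(sigma)},
                    {s, std::log(sigma) + 0.1}};
  double f[3];
  for (int i = 0; i < 3; ++i) f[i] = -rician_loglik(x, p[i][0], std::exp(p[i][1]));
  int it = 0;
  while (it++ < maxit) {
    // order: f[lo] <= f[mid] <= f[hi]
    int lo = 0, hi = 0;
    for (int i = 1; i < 3; ++i) { if (f[i] < f[lo]) lo = i; if (f[i] > f[hi]) hi = i; }
    int mid = 3 - lo - hi; if (lo == hi) { mid = 1; hi = 2; }
    if (std::fabs(f[hi] - f[lo]) < tol * (std::fabs(f[lo]) + tol)) break;
    double cen[2] = {0.0, 0.0};
    for (int i = 0; i < 3; ++i) if (i != hi) { cen[0] += p[i][0]; cen[1] += p[i][1]; }
    cen[0] *= 0.5; cen[1] *= 0.5;
    double refl[2] = {2 * cen[0] - p[hi][0], 2 * cen[1] - p[hi][1]};
    double fr = -rician_loglik(x, refl[0], std::exp(refl[1]));
    if (fr < f[lo]) {
      double exp2[2] = {3 * cen[0] - 2 * p[hi][0], 3 * cen[1] - 2 * p[hi][1]};
      double fe = -rician_loglik(x, exp2[0], std::exp(exp2[1]));
      if (fe < fr) { p[hi][0] = exp2[0]; p[hi][1] = exp2[1]; f[hi] = fe; }
      else { p[hi][0] = refl[0]; p[hi][1] = refl[1]; f[hi] = fr; }
    } else if (fr < f[mid]) {
      p[hi][0] = refl[0]; p[hi][1] = refl[1]; f[hi] = fr;
    } else {
      double con[2] = {0.5 * (cen[0] + p[hi][0]), 0.5 * (cen[1] + p[hi][1])};
      double fc = -rician_loglik(x, con[0], std::exp(con[1]));
      if (fc < f[hi]) { p[hi][0] = con[0]; p[hi][1] = con[1]; f[hi] = fc; }
      else { // shrink toward best
        for (int i = 0; i < 3; ++i) {
          if (i == lo) continue;
          p[i][0] = 0.5 * (p[i][0] + p[lo][0]);
          p[i][1] = 0.5 * (p[i][1] + p[lo][1]);
          f[i] = -rician_loglik(x, p[i][0], std::exp(p[i][1]));
        }
      }
    }
  }
  int lo = 0;
  for (int i = 1; i < 3; ++i) if (f[i] < f[lo]) lo = i;
  s = std::fabs(p[lo][0]);
  sigma = std::exp(p[lo][1]);
  ll = -f[lo];
  ok = std::isfinite(ll);
}

// Moment-based starting values; tries a diffuse (Rayleigh-like) and a
// coherent start and keeps the better one.
static void rician_fit_core(const std::vector<double>& x, double& s, double& sigma,
                            double& ll, bool& ok) {
  const int n = (int)x.size();
  double m1 = 0.0, m2 = 0.0;
  for (double xi : x) { m1 += xi; m2 += xi * xi; }
  m1 /= n; m2 /= n;
  double var = std::max(m2 - m1 * m1, 1e-300);
  double s_a = 0.1 * std::sqrt(m2), sg_a = std::sqrt(m2 / 2.0);
  double s_b = m1, sg_b = std::sqrt(var);
  double fa = rician_loglik(x, s_a, sg_a);
  double fb = rician_loglik(x, s_b, sg_b);
  if (fb > fa) { s = s_b; sigma = sg_b; } else { s = s_a; sigma = sg_a; }
  nelder_mead(x, s, sigma, ll, ok);
}

// [[Rcpp::export]]
List rician_mle_cpp(NumericVector x) {
  std::vector<double> v(x.begin(), x.end());
  double s = 0, sigma = 1, ll = 0; bool ok = false;
  rician_fit_core(v, s, sigma, ll, ok);
  return List::create(_["s"] = s, _["sigma"] = sigma,
                      _["loglik"] = ll + loglik_const(v), _["converged"] = ok);
}

// Sliding-block Rician fit over an envelope image. A block of size
// block_rows x block_cols is valid when every cell of `mask` under it is
// TRUE and every envelope value is > 0; its fitted s lands on the block
// midpoint. Returns the s map, a sigma map and the validity mask.
// [[Rcpp::export]]
List rician_map_cpp(NumericMatrix env, LogicalMatrix mask,
                    int block_rows, int block_cols) {
  const int H = env.nrow(), W = env.ncol();
  NumericMatrix vals(H, W), sig(H, W);
  LogicalMatrix valid(H, W);
  std::fill(vals.begin(), vals.end(), NA_REAL);
  std::fill(sig.begin(), sig.end(), NA_REAL);
  // integral image of the mask for O(1) full-block tests
  std::vector<int> I((H + 1) * (W + 1), 0);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      I[(i + 1) * (W + 1) + (j + 1)] = (mask(i, j) ? 1 : 0)
        + I[i * (W + 1) + (j + 1)] + I[(i + 1) * (W + 1) + j] - I[i * (W + 1) + j];
  const int nblk = block_rows * block_cols;
  std::vector<double> buf(nblk);
  for (int i = 0; i + block_rows <= H; ++i) {
    for (int j = 0; j + block_cols <= W; ++j) {
      int covered = I[(i + block_rows) * (W + 1) + (j + block_cols)]
        - I[i * (W + 1) + (j + block_cols)]
        - I[(i + block_rows) * (W + 1) + j] + I[i * (W + 1) + j];
      if (covered != nblk) continue;
      bool pos = true; int k = 0;
      for (int jj = j; jj < j + block_cols && pos; ++jj)
        for (int ii = i; ii < i + block_rows; ++ii) {
          double e = env(ii, jj);
          if (!(e > 0.0)) { pos = false; break; }
          buf[k++] = e;
        }
      if (!pos) continue;
      double s = 0, sigma = 1, ll = 0; bool ok = false;
      rician_fit_core(buf, s, sigma, ll, ok);
      if (!ok) continue;
      int ci = i + block_rows / 2, cj = j + block_cols / 2;
      vals(ci, cj) = s;
      sig(ci, cj) = sigma;
      valid(ci, cj) = true;
    }
  }
  return List::create(_["values"] = vals, _["sigma"] = sig, _["valid"] = valid);
}
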