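// Just-in-time SAGA for class-weighted L1-penalized logistic regression.
//
// Minimizes (1/n) sum_i w_{y_i} * nll_i(theta) + (lambda/n) * ||beta||_1
// (equivalently: sum-scale weighted NLL + lambda * ||beta||_1), with an
// unpenalized intercept. The per-sample gradient of the logistic loss is
// a scalar times x_i, so the SAGA gradient table stores one scalar per
// sample. Coordinates outside the support of the current sample receive
// their (constant-between-touches) drift + soft-threshold updates lazily
// in closed form, making the per-step cost proportional to nnz(x_i).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
using namespace Rcpp;

static inline double soft(double z, double c) {
  if (z > c) return z - c;
  if (z < -c) return z + c;
  return 0.0;
}

// Apply t iterations of theta <- soft(theta - d, c) in O(1).
// The map is piecewise linear with slope 1; the trajectory passes through
// at most three regimes (linear drift on the side where |theta - d| > c,
// the absorbing/jump region |theta - d| <= c, then a linear tail when the
// drift exceeds the threshold).
static double lazy_prox(double th, double d, double c, long t) {
  if (t <= 0) return th;
  if (c <= 0.0) return th - (double)t * d;  // lambda = 0: pure drift
  if (d < 0) return -lazy_prox(-th, -d, c, t);
  // d >= 0, c > 0
  if (th > c + d) {  // decreasing by (d+c) per step while theta > c+d
    double s = d + c;
    long k = (long)std::ceil((th - (c + d)) / s);
    if (k < 1) k = 1;
    if (k > t) k = t;
    th -= (double)k * s;
    t -= k;
    if (t == 0) return th;
  }
  if (th < d - c) {  // theta - d < -c
    double delta = d - c;
    if (delta > 0.0) return th - (double)t * delta;  // drifts to -inf
    if (delta == 0.0) return th;                      // fixed
    // delta < 0: increases by (c-d) per step until th >= d-c
    double step = c - d;
    long k = (long)std::ceil(((d - c) - th) / step);
    if (k < 1) k = 1;
    if (k > t) k = t;
    th += (double)k * step;
    t -= k;
    if (t == 0) return th;
  }
  // now d - c <= th <= c + d: next step maps to exactly 0
  th = 0.0;
  t -= 1;
  if (t == 0 || d <= c) return 0.0;  // |drift| <= threshold: 0 is fixed
  return -(double)t * (d - c);       // escapes along the negative branch
}

static inline double nll_log1pexp(double z) {
  // log(1 + exp(z)), stable
  if (z > 35.0) return z;
  if (z < -35.0) return std::exp(z);
  return std::log1p(std::exp(z));
}

// Xt: dgCMatrix of size d x n (columns are samples), WITHOUT the
// constant-1 intercept coordinate (handled separately, unpenalized).
// [[Rcpp::export]]
List saga_fit_cpp(S4 Xt, NumericVector y, double w0, double w1,
                  double lambda, NumericVector beta0, double intercept0,
                  int max_epochs, double tol, int seed,
                  int obj_every = 1) {
  IntegerVector dims = Xt.slot("Dim");
  int d = dims[0], n = dims[1];
  IntegerVector P = Xt.slot("p");
  IntegerVector I = Xt.slot("i");
  NumericVector X = Xt.slot("x");
  const int* p = INTEGER(P);
  const int* ridx = INTEGER(I);
  const double* xv = REAL(X);

  std::vector<double> beta(beta0.begin(), beta0.end());
  double b0 = intercept0;
  std::vector<double> w(n);
  for (int i = 0; i < n; ++i) w[i] = y[i] == 1.0 ? w1 : w0;

  // step size from the max per-sample curvature bound (incl. intercept)
  double Lmax = 0.0;
  for (int i = 0; i < n; ++i) {
    double s2 = 1.0;
    for (int t = p[i]; t < p[i + 1]; ++t) s2 += xv[t] * xv[t];
    double Li = 0.25 * w[i] * s2;
    if (Li > Lmax) Lmax = Li;
  }
  if (Lmax <= 0.0) Lmax = 1.0;
  double gamma = 1.0 / (3.0 * Lmax);
  double lam_mean = lambda / (double)n;
  double thr = gamma * lam_mean;

  // gradient table (scalars) and running average gradient
  std::vector<double> alpha(n);
  std::vector<double> avg(d, 0.0);
  double avg0 = 0.0;
  std::vector<long> last(d, 0);

  // initialization pass at theta0
  for (int i = 0; i < n; ++i) {
    double z = b0;
    for (int t = p[i]; t < p[i + 1]; ++t) z += xv[t] * beta[ridx[t]];
    double pr = 1.0 / (1.0 + std::exp(-z));
    alpha[i] = w[i] * (pr - y[i]);
    for (int t = p[i]; t < p[i + 1]; ++t) avg[ridx[t]] += alpha[i] * xv[t];
    avg0 += alpha[i];
  }
  for (int j = 0; j < d; ++j) avg[j] /= (double)n;
  avg0 /= (double)n;

  std::mt19937 rng((unsigned)seed);

  double obj_prev = R_PosInf;
  double obj = R_PosInf;
  bool converged = false;
  int epoch = 0;
  long step = 0;
  for (epoch = 0; epoch < max_epochs; ++epoch) {
    for (int it = 0; it < n; ++it) {
      int i = (int)(rng() % (unsigned)n);
      // JIT catch-up for this sample's support, fused with the dot
      // product
      double z = b0;
      for (int t = p[i]; t < p[i + 1]; ++t) {
        int j = ridx[t];
        double bj = lazy_prox(beta[j], gamma * avg[j], thr,
                              step - last[j]);
        beta[j] = bj;
        last[j] = step;
        z += xv[t] * bj;
      }
      double pr = 1.0 / (1.0 + std::exp(-z));
      double anew = w[i] * (pr - y[i]);
      double da = anew - alpha[i];
      for (int t = p[i]; t < p[i + 1]; ++t) {
        int j = ridx[t];
        double g = da * xv[t] + avg[j];
        beta[j] = soft(beta[j] - gamma * g, thr);
        last[j] = step + 1;
        avg[j] += da * xv[t] / (double)n;
      }
      b0 -= gamma * (da + avg0);
      avg0 += da / (double)n;
      alpha[i] = anew;
      ++step;
    }
    if ((epoch + 1) % obj_every != 0 && epoch + 1 < max_epochs) continue;
    // full catch-up, then objective (sum scale)
    for (int j = 0; j < d; ++j) {
      beta[j] = lazy_prox(beta[j], gamma * avg[j], thr, step - last[j]);
      last[j] = step;
    }
    obj = 0.0;
    for (int i = 0; i < n; ++i) {
      double z = b0;
      for (int t = p[i]; t < p[i + 1]; ++t) z += xv[t] * beta[ridx[t]];
      // nll = -[y log sig(z) + (1-y) log(1-sig(z))]
      obj += w[i] * (y[i] == 1.0 ? nll_log1pexp(-z) : nll_log1pexp(z));
    }
    double pen = 0.0;
    for (int j = 0; j < d; ++j) pen += std::fabs(beta[j]);
    obj += lambda * pen;
    if (std::fabs(obj_prev - obj) < tol * std::max(1.0, std::fabs(obj))) {
      converged = true;
      ++epoch;
      break;
    }
    obj_prev = obj;
  }

  int nnz = 0;
  for (int j = 0; j < d; ++j)
    if (beta[j] != 0.0) ++nnz;
  return List::create(_["beta"] = wrap(beta), _["intercept"] = b0,
                      _["objective"] = obj, _["epochs"] = epoch,
                      _["converged"] = converged, _["support"] = nnz,
                      _["gamma"] = gamma);
}
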