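// Data-augmentation cell sweeps for the Gibbs samplers.  Each sweep makes one
// pass over the N x K response matrix, redrawing the latent informativeness
// indicators Z (response-mixture model only) and the augmented propensities
// Y1 (first node) and Y2 (second node), and accumulating the per-item,
// per-category min/max of Y2 needed for the threshold updates.  All
// randomness comes from R's RNG so runs are reproducible under set.seed().

#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

static const double PROB_FLOOR = 1e-300;

// standard normal truncated to (a, b), inverse-CDF with tail fallbacks
static double rtnorm_std1(double a, double b, double u) {
  double z;
  if (R_FINITE(a) && a > 3.5) {               // region in the upper tail
    double qa = R::pnorm(a, 0.0, 1.0, 0, 0);
    double qb = R_FINITE(b) ? R::pnorm(b, 0.0, 1.0, 0, 0) : 0.0;
    z = R::qnorm(qa - u * (qa - qb), 0.0, 1.0, 0, 0);
    if (!R_FINITE(z)) {                       // exponential tail approximation
      double frac = R_FINITE(b) ? -expm1(-a * (b - a)) : 1.0;
      z = a - log1p(-u * frac) / a;
    }
  } else if (R_FINITE(b) && b < -3.5) {       // mirror of the above
    double mb = -b, ma = -a;
    double qb = R::pnorm(mb, 0.0, 1.0, 0, 0);
    double qa = R_FINITE(a) ? R::pnorm(ma, 0.0, 1.0, 0, 0) : 0.0;
    z = R::qnorm(qb - u * (qb - qa), 0.0, 1.0, 0, 0);
    if (!R_FINITE(z)) {
      double frac = R_FINITE(a) ? -expm1(-mb * (ma - mb)) : 1.0;
      z = mb - log1p(-u * frac) / mb;
    }
    z = -z;
  } else {
    double pa = R_FINITE(a) ? R::pnorm(a, 0.0, 1.0, 1, 0) : 0.0;
    double pb = R_FINITE(b) ? R::pnorm(b, 0.0, 1.0, 1, 0) : 1.0;
    z = R::qnorm(pa + u * (pb - pa), 0.0, 1.0, 1, 0);
  }
  if (R_FINITE(a) && z <= a) z = a + 1e-12;
  if (R_FINITE(b) && z >= b) z = b - 1e-12;
  return z;
}

// N(mean, 1) truncated to (lo, hi)
static inline double rtnorm1(double mean, double lo, double hi) {
  return mean + rtnorm_std1(R_FINITE(lo) ? lo - mean : R_NegInf,
                            R_FINITE(hi) ? hi - mean : R_PosInf,
                            unif_rand());
}

static inline void track(NumericMatrix& mn, NumericMatrix& mx,
                         int i, int cat, double y) {
  if (y < mn(i, cat)) mn(i, cat) = y;
  if (y > mx(i, cat)) mx(i, cat) = y;
}

static void reset_minmax(NumericMatrix& mn, NumericMatrix& mx) {
  std::fill(mn.begin(), mn.end(), R_PosInf);
  std::fill(mx.begin(), mx.end(), R_NegInf);
}

// [[Rcpp::export]]
void sweep_rmm(const IntegerMatrix X, int m,
               IntegerMatrix Z, NumericMatrix Y1, NumericMatrix Y2,
               const NumericVector theta1, const NumericVector theta2,
               double alpha1, const NumericVector beta,
               const NumericVector alpha2, const NumericMatrix delta,
               NumericMatrix minY2, NumericMatrix maxY2) {
  int N = X.nrow(), K = X.ncol(), h = delta.ncol();
  reset_minmax(minY2, maxY2);
  for (int i = 0; i < K; i++) {
    double b = beta[i], a2 = alpha2[i];
    for (int p = 0; p < N; p++) {
      int x = X(p, i);
      double eta1 = -alpha1 * theta1[p] - b;
      double eta2 = a2 * theta2[p];
      int z = 1;
      if (x == m) { // redraw the path indicator for an observed middle score
        double p1 = R::pnorm(eta1, 0.0, 1.0, 1, 0);
        double pm = R::pnorm(eta2 - delta(i, m - 1), 0.0, 1.0, 1, 0)
                  - R::pnorm(eta2 - delta(i, m), 0.0, 1.0, 1, 0);
        double num = p1 * pm;
        double den = (1.0 - p1) + num;
        if (den < PROB_FLOOR) den = PROB_FLOOR;
        z = (unif_rand() < num / den) ? 1 : 0;
        Z(p, i) = z;
      }
      // first-node propensity: positive iff the response was informative
      Y1(p, i) = z ? rtnorm1(eta1, 0.0, R_PosInf)
                   : rtnorm1(eta1, R_NegInf, 0.0);
      if (z) { // second-node propensity within the observed category's band
        double lo = (x == 0) ? R_NegInf : delta(i, x - 1);
        double hi = (x == h) ? R_PosInf : delta(i, x);
        double y2 = rtnorm1(eta2, lo, hi);
        Y2(p, i) = y2;
        track(minY2, maxY2, i, x, y2);
      }
    }
  }
}

// [[Rcpp::export]]
void sweep_grm(const IntegerMatrix X, NumericMatrix Y2,
               const NumericVector theta2, const NumericVector alpha2,
               const NumericMatrix delta,
               NumericMatrix minY2, NumericMatrix maxY2) {
  int N = X.nrow(), K = X.ncol(), h = delta.ncol();
  reset_minmax(minY2, maxY2);
  for (int i = 0; i < K; i++) {
    double a2 = alpha2[i];
    for (int p = 0; p < N; p++) {
      int x = X(p, i);
      double lo = (x == 0) ? R_NegInf : delta(i, x - 1);
      double hi = (x == h) ? R_PosInf : delta(i, x);
      double y2 = rtnorm1(a2 * theta2[p], lo, hi);
      Y2(p, i) = y2;
      track(minY2, maxY2, i, x, y2);
    }
  }
}

// [[Rcpp::export]]
void sweep_irtree(const IntegerMatrix X, int m,
                  NumericMatrix Y1, NumericMatrix Y2,
                  const NumericVector theta1, const NumericVector theta2,
                  double alpha1, const NumericVector beta,
                  const NumericVector alpha2, const NumericMatrix delta,
                  NumericMatrix minY2, NumericMatrix maxY2) {
  int N = X.nrow(), K = X.ncol(), hr = delta.ncol(); // hr = h - 1 thresholds
  reset_minmax(minY2, maxY2);
  for (int i = 0; i < K; i++) {
    double b = beta[i], a2 = alpha2[i];
    for (int p = 0; p < N; p++) {
      int x = X(p, i);
      int z = (x != m);                       // path fully observed
      double eta1 = -alpha1 * theta1[p] - b;
      Y1(p, i) = z ? rtnorm1(eta1, 0.0, R_PosInf)
                   : rtnorm1(eta1, R_NegInf, 0.0);
      if (z) {
        int xr = (x > m) ? x - 1 : x;         // scores remapped to 0..h-1
        double lo = (xr == 0) ? R_NegInf : delta(i, xr - 1);
        double hi = (xr == hr) ? R_PosInf : delta(i, xr);
        double y2 = rtnorm1(a2 * theta2[p], lo, hi);
        Y2(p, i) = y2;
        track(minY2, maxY2, i, xr, y2);
      }
    }
  }
}
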