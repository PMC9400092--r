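// Hot loops of the sampler and kernel assembly.
// All randomness goes through R's RNG so set.seed() governs every draw.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// squared distance between row x and row m of xu
static inline double sqdist(const arma::rowvec& x, const arma::mat& xu, arma::uword m) {
  double s = 0.0;
  for (arma::uword d = 0; d < x.n_elem; ++d) {
    double diff = x[d] - xu(m, d);
    s += diff * diff;
  }
  return s;
}

// force at a single point: f_k(x) = sum_m alpha_m * (h2/ell2) * (x_k - xu_{m,k}) * exp(-0.5 |x-xu_m|^2/ell2)
// with alpha = K^{-1} u
static inline void force_at(const arma::rowvec& x, const arma::mat& xu,
                            const arma::vec& alpha, double h2, double ell2,
                            arma::rowvec& f) {
  f.zeros();
  const double c = h2 / ell2;
  for (arma::uword m = 0; m < xu.n_rows; ++m) {
    double w = alpha[m] * c * std::exp(-0.5 * sqdist(x, xu, m) / ell2);
    for (arma::uword d = 0; d < x.n_elem; ++d)
      f[d] += w * (x[d] - xu(m, d));
  }
}

// [[Rcpp::export]]
arma::mat cpp_se_kernel(const arma::mat& a, const arma::mat& b, double h2, double ell) {
  const double ell2 = ell * ell;
  arma::mat out(a.n_rows, b.n_rows);
  for (arma::uword i = 0; i < a.n_rows; ++i) {
    arma::rowvec ai = a.row(i);
    for (arma::uword j = 0; j < b.n_rows; ++j)
      out(i, j) = h2 * std::exp(-0.5 * sqdist(ai, b, j) / ell2);
  }
  return out;
}

// Flattened derivative cross-covariance: row index (i*D + d) holds the
// covariance between the force along dimension d at point i and u at the
// inducing points (dimension-fastest packing).
// [[Rcpp::export]]
arma::mat cpp_kstar_flat(const arma::mat& pts, const arma::mat& xu, double h2, double ell) {
  const double ell2 = ell * ell;
  const arma::uword D = pts.n_cols;
  arma::mat out(pts.n_rows * D, xu.n_rows);
  for (arma::uword i = 0; i < pts.n_rows; ++i) {
    arma::rowvec xi = pts.row(i);
    for (arma::uword m = 0; m < xu.n_rows; ++m) {
      double w = (h2 / ell2) * std::exp(-0.5 * sqdist(xi, xu, m) / ell2);
      for (arma::uword d = 0; d < D; ++d)
        out(i * D + d, m) = w * (xi[d] - xu(m, d));
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_force_batch(const arma::mat& pts, const arma::mat& xu,
                          const arma::vec& alpha, double h2, double ell) {
  const double ell2 = ell * ell;
  arma::mat out(pts.n_rows, pts.n_cols);
  arma::rowvec f(pts.n_cols);
  for (arma::uword i = 0; i < pts.n_rows; ++i) {
    arma::rowvec xi = pts.row(i);
    force_at(xi, xu, alpha, h2, ell2, f);
    out.row(i) = f;
  }
  return out;
}

// One sequential single-site Metropolis-Hastings sweep over the latent
// positions x_1..x_N.  Targets, per site n,
//   n = 1:  N(x1; 0, 2*tau*kT/zeta) * N(x2; x1 + (tau/zeta) f(x1), g2) * N(y1; x1, s2)
//   1<n<N:  N(xn; x_{n-1} + (tau/zeta) f(x_{n-1}), g2) * N(x_{n+1}; xn + (tau/zeta) f(xn), g2) * N(yn; xn, s2)
//   n = N:  backward transition * measurement only
// with g2 = 2*tau*kT/zeta.  Proposal: isotropic Gaussian random walk.
// [[Rcpp::export]]
List cpp_sweep_positions(const arma::mat& x_in, const arma::mat& y,
                         const arma::mat& xu, const arma::vec& alpha,
                         double h2, double ell, double tau, double kT,
                         double zeta, double sigma2, double prop_sd) {
  const double ell2 = ell * ell;
  const double g2 = 2.0 * tau * kT / zeta;
  const double drift = tau / zeta;
  const arma::uword N = x_in.n_rows, D = x_in.n_cols;
  arma::mat x = x_in;

  // forces at current positions, updated on acceptance
  arma::mat fcur = cpp_force_batch(x, xu, alpha, h2, ell);

  arma::rowvec fprop(D);
  int accepted = 0;
  for (arma::uword n = 0; n < N; ++n) {
    arma::rowvec cur = x.row(n);
    arma::rowvec prop(D);
    for (arma::uword d = 0; d < D; ++d)
      prop[d] = cur[d] + prop_sd * R::norm_rand();

    double dlog = 0.0;
    // backward term (or x1 prior)
    if (n == 0) {
      dlog += (arma::dot(cur, cur) - arma::dot(prop, prop)) / (2.0 * g2);
    } else {
      arma::rowvec mprev = x.row(n - 1) + drift * fcur.row(n - 1);
      arma::rowvec rc = cur - mprev, rp = prop - mprev;
      dlog += (arma::dot(rc, rc) - arma::dot(rp, rp)) / (2.0 * g2);
    }
    // forward term: force at x_n changes with the proposal
    if (n + 1 < N) {
      force_at(prop, xu, alpha, h2, ell2, fprop);
      arma::rowvec nxt = x.row(n + 1);
      arma::rowvec rc = nxt - (cur + drift * fcur.row(n));
      arma::rowvec rp = nxt - (prop + drift * fprop);
      dlog += (arma::dot(rc, rc) - arma::dot(rp, rp)) / (2.0 * g2);
    }
    // measurement term
    {
      arma::rowvec rc = y.row(n) - cur, rp = y.row(n) - prop;
      dlog += (arma::dot(rc, rc) - arma::dot(rp, rp)) / (2.0 * sigma2);
    }

    if (dlog >= 0.0 || R::unif_rand() < std::exp(dlog)) {
      x.row(n) = prop;
      if (n + 1 < N) fcur.row(n) = fprop;
      ++accepted;
    }
  }
  return List::create(_["x"] = x, _["accepted"] = accepted);
}

// Forward-Euler overdamped Langevin integration against a force field defined
// by the inducing-point representation (used by benchmark re-simulation; the
// general simulator with an arbitrary R potential lives in R code).
// [[Rcpp::export]]
arma::mat cpp_simulate_ski(const arma::mat& x0, const arma::mat& xu,
                           const arma::vec& alpha, double h2, double ell,
                           double tau, double kT, double zeta, int n_steps) {
  const double ell2 = ell * ell;
  const double g = std::sqrt(2.0 * kT * tau / zeta);
  const double drift = tau / zeta;
  const arma::uword D = x0.n_cols;
  arma::mat out(n_steps, D);
  out.row(0) = x0.row(0);
  arma::rowvec f(D);
  for (int n = 1; n < n_steps; ++n) {
    arma::rowvec prev = out.row(n - 1);
    force_at(prev, xu, alpha, h2, ell2, f);
    for (arma::uword d = 0; d < D; ++d)
      out(n, d) = prev[d] + drift * f[d] + g * R::norm_rand();
  }
  return out;
}
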