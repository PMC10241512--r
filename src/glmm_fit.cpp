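// Penalized-IRLS core for mixed models with per-session (grouped) random
// intercept + slopes and a *diagonal* random-effect covariance.
//
// Parameterization follows the relative-covariance-factor convention:
// eta = X beta + Z_s diag(theta) b_s,  b_s ~ N(0, I) spherical.
// For the gaussian family theta is in units of the residual SD (so the
// reported random-effect SDs are theta * sigma).
//
// The profiled objective optimized over theta is a Laplace-class deviance:
// the (beta, b) mode is found by penalized IRLS and the log-determinant of
// the per-session conditional precision is added at the mode.
//
// Data must arrive sorted by session; `starts` holds the first row of each
// session plus a terminal n.

#include <RcppArmadillo.h>
using namespace arma;

static const double ETA_CLAMP = 30.0;

struct PirlsResult {
  vec beta;
  mat b;          // q x S spherical random effects
  double pdev;    // -2 cond. loglik + |b|^2 (binomial); penalized wRSS (gaussian)
  double logdet;  // sum_s log det(A_s) at the mode
  mat schur;      // X'WX - sum B' A^-1 B  (for Wald vcov of beta)
  bool converged;
  int iter;
};

static inline double binom_m2ll(const vec& y, const vec& eta, const vec& w) {
  // -2 * sum w * (y*log(mu) + (1-y)*log(1-mu)), numerically via log1p(exp())
  double s = 0.0;
  for (uword i = 0; i < y.n_elem; ++i) {
    if (w[i] == 0.0) continue;
    double e = eta[i];
    // log(1+exp(e)) stable
    double lse = (e > 0) ? e + std::log1p(std::exp(-e)) : std::log1p(std::exp(e));
    s += w[i] * (y[i] * e - lse);
  }
  return -2.0 * s;
}

// One penalized weighted least-squares solve given working weights Ww and
// working response contribution Wz (passed as W*z to avoid 0/0).
// Fills beta, b; returns false on a singular system.
static bool pwls_solve(const mat& X, const mat& Z, const uvec& starts,
                       const vec& theta, const vec& Ww, const vec& Wz,
                       vec& beta, mat& b, double& logdet, mat& schur_out) {
  const uword p = X.n_cols, q = Z.n_cols, S = starts.n_elem - 1;
  mat XtWX(p, p, fill::zeros);
  vec XtWz(p, fill::zeros);
  mat S1(p, p, fill::zeros);
  vec S2(p, fill::zeros);
  std::vector<mat> Ainv_list(S);
  std::vector<mat> B_list(S);
  std::vector<vec> c_list(S);
  logdet = 0.0;
  for (uword s = 0; s < S; ++s) {
    uword i0 = starts[s], i1 = starts[s + 1] - 1;
    mat Xs = X.rows(i0, i1);
    mat ZLs = Z.rows(i0, i1);
    ZLs.each_row() %= theta.t();
    vec ws = Ww.subvec(i0, i1);
    vec wzs = Wz.subvec(i0, i1);
    mat ZtW = ZLs.t();
    ZtW.each_row() %= ws.t();          // q x n_s: Lam Z' W
    mat A = ZtW * ZLs; A.diag() += 1.0;
    mat B = ZtW * Xs;                   // q x p
    vec c = ZLs.t() * wzs;              // q
    mat Ainv;
    if (!inv_sympd(Ainv, A)) return false;
    double ld, sgn;
    log_det(ld, sgn, A);
    logdet += ld;
    mat XtWs = Xs.t(); XtWs.each_row() %= ws.t();
    XtWX += XtWs * Xs;
    XtWz += Xs.t() * wzs;
    S1 += B.t() * (Ainv * B);
    S2 += B.t() * (Ainv * c);
    Ainv_list[s] = Ainv; B_list[s] = B; c_list[s] = c;
  }
  mat M = XtWX - S1;
  vec rhs = XtWz - S2;
  if (!solve(beta, M, rhs, solve_opts::likely_sympd + solve_opts::no_approx))
    return false;
  for (uword s = 0; s < S; ++s)
    b.col(s) = Ainv_list[s] * (c_list[s] - B_list[s] * beta);
  schur_out = M;
  return true;
}

static vec linpred(const mat& X, const mat& Z, const uvec& starts,
                   const vec& theta, const vec& beta, const mat& b) {
  vec eta = X * beta;
  const uword S = starts.n_elem - 1;
  for (uword s = 0; s < S; ++s) {
    uword i0 = starts[s], i1 = starts[s + 1] - 1;
    eta.subvec(i0, i1) += Z.rows(i0, i1) * (theta % b.col(s));
  }
  return clamp(eta, -ETA_CLAMP, ETA_CLAMP);
}

// PIRLS for the binomial-logit family; for gaussian a single solve suffices.
static PirlsResult pirls(const mat& X, const mat& Z, const vec& y, const vec& w,
                         const uvec& starts, const vec& theta, int family,
                         vec beta0, mat b0, int maxit, double tol) {
  PirlsResult out;
  const uword S = starts.n_elem - 1;
  out.converged = false; out.iter = 0;

  if (family == 1) { // gaussian: W = w, z = y
    vec Wz = w % y;
    vec beta; mat b(Z.n_cols, S, fill::zeros);
    double logdet; mat schur;
    if (!pwls_solve(X, Z, starts, theta, w, Wz, beta, b, logdet, schur)) {
      out.pdev = datum::inf; return out;
    }
    vec eta = X * beta;
    for (uword s = 0; s < S; ++s) {
      uword i0 = starts[s], i1 = starts[s + 1] - 1;
      eta.subvec(i0, i1) += Z.rows(i0, i1) * (theta % b.col(s));
    }
    vec r = y - eta;
    out.pdev = dot(w, r % r) + accu(b % b);
    out.logdet = logdet; out.beta = beta; out.b = b; out.schur = schur;
    out.converged = true; out.iter = 1;
    return out;
  }

  // binomial
  vec beta = beta0;
  mat b = b0;
  vec eta = linpred(X, Z, starts, theta, beta, b);
  double pdev = binom_m2ll(y, eta, w) + accu(b % b);
  double logdet = 0.0; mat schur;
  for (int it = 0; it < maxit; ++it) {
    vec mu = 1.0 / (1.0 + exp(-eta));
    vec Ww = w % mu % (1.0 - mu);
    // W*z = W*eta + w*(y - mu)
    vec Wz = Ww % eta + w % (y - mu);
    vec beta_new; mat b_new(Z.n_cols, S, fill::zeros);
    if (!pwls_solve(X, Z, starts, theta, Ww, Wz, beta_new, b_new, logdet, schur)) {
      out.pdev = datum::inf; out.beta = beta; out.b = b; return out;
    }
    // step-halving on the penalized deviance
    double step = 1.0; double pdev_new = datum::inf;
    vec beta_try; mat b_try; vec eta_try;
    for (int h = 0; h < 12; ++h) {
      beta_try = beta + step * (beta_new - beta);
      b_try = b + step * (b_new - b);
      eta_try = linpred(X, Z, starts, theta, beta_try, b_try);
      pdev_new = binom_m2ll(y, eta_try, w) + accu(b_try % b_try);
      if (pdev_new <= pdev + 1e-10) break;
      step *= 0.5;
    }
    beta = beta_try; b = b_try; eta = eta_try;
    out.iter = it + 1;
    if (std::abs(pdev - pdev_new) < tol * (std::abs(pdev_new) + 0.1)) {
      pdev = pdev_new; out.converged = true; break;
    }
    pdev = pdev_new;
  }
  // refresh logdet/schur at the mode
  vec mu = 1.0 / (1.0 + exp(-eta));
  vec Ww = w % mu % (1.0 - mu);
  vec Wz = Ww % eta + w % (y - mu);
  vec beta_m; mat b_m(Z.n_cols, S, fill::zeros);
  pwls_solve(X, Z, starts, theta, Ww, Wz, beta_m, b_m, logdet, schur);
  out.beta = beta; out.b = b; out.pdev = pdev;
  out.logdet = logdet; out.schur = schur;
  return out;
}

// [[Rcpp::export(name = ".glmm_profiled_dev")]]
double glmm_profiled_dev(const arma::mat& X, const arma::mat& Z,
                         const arma::vec& y, const arma::vec& w,
                         const arma::uvec& starts, const arma::vec& theta,
                         int family, int maxit, double tol) {
  vec th = abs(theta);
  vec beta0(X.n_cols, fill::zeros);
  mat b0(Z.n_cols, starts.n_elem - 1, fill::zeros);
  PirlsResult r = pirls(X, Z, y, w, starts, th, family, beta0, b0, maxit, tol);
  if (!std::isfinite(r.pdev)) return 1e12;
  if (family == 1) {
    double nw = accu(w);
    return r.logdet + nw * (1.0 + std::log(2.0 * datum::pi * r.pdev / nw));
  }
  return r.pdev + r.logdet;
}

// [[Rcpp::export(name = ".glmm_solve")]]
Rcpp::List glmm_solve(const arma::mat& X, const arma::mat& Z,
                      const arma::vec& y, const arma::vec& w,
                      const arma::uvec& starts, const arma::vec& theta,
                      int family, int maxit, double tol,
                      const arma::vec& beta0, const arma::mat& b0) {
  vec th = abs(theta);
  PirlsResult r = pirls(X, Z, y, w, starts, th, family, beta0, b0, maxit, tol);
  double sigma = 1.0, dev;
  if (family == 1) {
    double nw = accu(w);
    sigma = std::sqrt(r.pdev / nw);
    dev = r.logdet + nw * (1.0 + std::log(2.0 * datum::pi * r.pdev / nw));
  } else {
    dev = r.pdev + r.logdet;
  }
  mat vcov;
  bool ok = inv_sympd(vcov, r.schur);
  if (!ok) vcov = mat(X.n_cols, X.n_cols, fill::value(datum::nan));
  if (family == 1) vcov *= sigma * sigma;
  return Rcpp::List::create(
    Rcpp::Named("beta") = r.beta,
    Rcpp::Named("b") = r.b,
    Rcpp::Named("deviance") = dev,
    Rcpp::Named("pdev") = r.pdev,
    Rcpp::Named("sigma") = sigma,
    Rcpp::Named("vcov_beta") = vcov,
    Rcpp::Named("converged") = r.converged,
    Rcpp::Named("iter") = r.iter);
}

// Hierarchical bootstrap inner loop: multinomial case weights per session are
// drawn in R (so the master seed governs them); this refits fixed effects and
// spherical modes for each weight vector at fixed theta, warm-starting from
// the full-data solution.
// [[Rcpp::export(name = ".glmm_boot_fixed_theta")]]
Rcpp::List glmm_boot_fixed_theta(const arma::mat& X, const arma::mat& Z,
                                 const arma::vec& y, const arma::mat& Wmat,
                                 const arma::uvec& starts, const arma::vec& theta,
                                 int family, int maxit, double tol,
                                 const arma::vec& beta0, const arma::mat& b0) {
  const uword R = Wmat.n_cols;
  mat draws(R, X.n_cols);
  std::vector<bool> conv(R);
  vec th = abs(theta);
  for (uword r = 0; r < R; ++r) {
    PirlsResult res = pirls(X, Z, y, Wmat.col(r), starts, th, family,
                            beta0, b0, maxit, tol);
    draws.row(r) = res.beta.t();
    conv[r] = res.converged && res.beta.is_finite();
  }
  return Rcpp::List::create(Rcpp::Named("draws") = draws,
                            Rcpp::Named("converged") = conv);
}
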