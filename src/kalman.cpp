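// Exact Gaussian likelihood of a zero-mean ARMA(p, q) process via the
// Kalman filter on the Harvey state-space form, with the concentrated
// innovation variance. The initial state covariance solves the stationary
// Lyapunov equation P = T P T' + R R' by a doubling iteration.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

static bool stationary_cov(const arma::mat& T, const arma::mat& V,
                           arma::mat& P) {
  arma::mat S = V;
  arma::mat A = T;
  for (int j = 0; j < 80; ++j) {
    arma::mat inc = A * S * A.t();
    S += inc;
    if (!S.is_finite()) return false;
    double mx = arma::abs(S).max();
    if (arma::abs(inc).max() < 1e-12 * std::max(1.0, mx)) {
      P = 0.5 * (S + S.t());
      return true;
    }
    A = A * A;
  }
  return false;
}

// Builds the transition matrix and runs the filter. Returns R_NilValue on
// numerical failure (non-stationary AR part, non-positive prediction
// variance), which the R caller treats as an invalid parameter point.
// [[Rcpp::export(name = ".kalman_arma")]]
SEXP kalman_arma(const arma::vec& w, const arma::vec& phi,
                 const arma::vec& theta, bool want_state) {
  const int n = w.n_elem;
  const int p = phi.n_elem, q = theta.n_elem;
  const int r = std::max(p, q + 1);

  arma::mat T(r, r, arma::fill::zeros);
  for (int i = 0; i < p; ++i) T(i, 0) = phi(i);
  for (int i = 0; i + 1 < r; ++i) T(i, i + 1) = 1.0;
  arma::vec Rv(r, arma::fill::zeros);
  Rv(0) = 1.0;
  for (int i = 0; i < q; ++i) Rv(i + 1) = theta(i);
  arma::mat RR = Rv * Rv.t();

  arma::mat P;
  if (!stationary_cov(T, RR, P)) return R_NilValue;

  arma::vec a(r, arma::fill::zeros);
  arma::vec v(n), Fv(n);
  double sumlog = 0.0, ssq = 0.0;
  for (int t = 0; t < n; ++t) {
    const double Ft = P(0, 0);
    if (!std::isfinite(Ft) || Ft <= 0.0) return R_NilValue;
    const double vt = w(t) - a(0);
    v(t) = vt;
    Fv(t) = Ft;
    sumlog += std::log(Ft);
    ssq += vt * vt / Ft;
    const arma::vec Pc = P.col(0);
    const arma::vec a_u = a + Pc * (vt / Ft);
    const arma::mat P_u = P - (Pc * P.row(0)) / Ft;
    a = T * a_u;
    P = T * P_u * T.t() + RR;
    P = 0.5 * (P + P.t());
  }
  const double sigma2 = ssq / n;
  const double loglik =
      -0.5 * n * (std::log(2.0 * M_PI) + 1.0 + std::log(sigma2)) -
      0.5 * sumlog;

  List out = List::create(Named("loglik") = loglik,
                          Named("sigma2") = sigma2,
                          Named("v") = v, Named("Fv") = Fv);
  if (want_state) {
    out["a"] = a;
    out["P"] = P;
    out["T"] = T;
    out["R"] = Rv;
  }
  return out;
}

// Conditional sum of squares objective (starting values only):
// 0.5 * m * log(ss / m) over t = p+1..n with zero-initialised errors.
// [[Rcpp::export(name = ".css_arma")]]
SEXP css_arma(const arma::vec& w, const arma::vec& phi,
              const arma::vec& theta) {
  const int n = w.n_elem;
  const int p = phi.n_elem, q = theta.n_elem;
  if (n <= p + 1) return R_NilValue;
  arma::vec e(n, arma::fill::zeros);
  double ss = 0.0;
  for (int t = p; t < n; ++t) {
    double acc = w(t);
    for (int i = 0; i < p; ++i) acc -= phi(i) * w(t - 1 - i);
    for (int j = 0; j < q && j < t - p; ++j) acc -= theta(j) * e(t - 1 - j);
    e(t) = acc;
    ss += acc * acc;
  }
  const int m = n - p;
  if (!(ss > 0.0) || !std::isfinite(ss)) return R_NilValue;
  return wrap(0.5 * m * std::log(ss / m));
}
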