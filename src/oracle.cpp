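// Independent reference optimizer used only by validation code: plain
// (non-accelerated) proximal-subgradient descent. The l1 part is handled by
// its exact prox; total-variation and quadratic parts enter the (sub)gradient.
// Shares no code path with the FISTA solver: its own objective evaluation,
// its own step-size rule (constant 1/L when the objective is prox-friendly,
// diminishing when a TV subgradient is involved), no momentum, no restarts.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// [[Rcpp::export]]
List prox_subgrad_oracle_cpp(const arma::mat &X, const arma::vec &y,
                             double w1, double w2, double wtv, double wlap,
                             const arma::imat &nbr_back, int n_iter) {
  const int p = X.n_cols;
  const double m = X.n_rows;
  const arma::mat Xt = X.t();

  // Lipschitz bound of the smooth quadratic part by power iteration on X'X
  arma::vec v(p, arma::fill::ones);
  v /= arma::norm(v);
  double eig = 0.0;
  for (int k = 0; k < 100; ++k) {
    arma::vec w = Xt * (X * v);
    double nw = arma::norm(w);
    if (nw == 0) break;
    eig = nw;
    v = w / nw;
  }
  double L = 2.0 * eig / m + 2.0 * w2 + 24.0 * wlap + 1e-12;
  const double step0 = 1.0 / L;

  auto objective = [&](const arma::vec &b) {
    arma::vec r = X * b - y;
    double val = arma::dot(r, r) / m + w1 * arma::norm(b, 1) +
                 w2 * arma::dot(b, b);
    if (wtv > 0 || wlap > 0) {
      for (int l = 0; l < 3; ++l)
        for (int vx = 0; vx < p; ++vx) {
          int bk = nbr_back(vx, l);
          if (bk > 0) {
            double d = b[vx] - b[bk - 1];
            if (wtv > 0) val += wtv * std::abs(d);
            if (wlap > 0) val += wlap * d * d;
          }
        }
    }
    return val;
  };

  arma::vec beta(p, arma::fill::zeros), g(p), best = beta;
  double best_obj = objective(beta);
  for (int k = 1; k <= n_iter; ++k) {
    g = (2.0 / m) * (Xt * (X * beta - y));
    if (w2 > 0) g += (2.0 * w2) * beta;
    if (wtv > 0 || wlap > 0) {
      for (int l = 0; l < 3; ++l)
        for (int vx = 0; vx < p; ++vx) {
          int bk = nbr_back(vx, l);
          if (bk > 0) {
            double d = beta[vx] - beta[bk - 1];
            double s = 0.0;
            if (wtv > 0) s += wtv * ((d > 0) - (d < 0));
            if (wlap > 0) s += 2.0 * wlap * d;
            g[vx] += s;
            g[bk - 1] -= s;
          }
        }
    }
    double s = (wtv > 0) ? step0 / std::sqrt(static_cast<double>(k)) : step0;
    beta -= s * g;
    if (w1 > 0) {
      double t = s * w1;
      for (int i = 0; i < p; ++i) {
        double a = std::abs(beta[i]) - t;
        beta[i] = a > 0 ? (beta[i] > 0 ? a : -a) : 0.0;
      }
    }
    double f = objective(beta);
    if (f < best_obj) {
      best_obj = f;
      best = beta;
    }
  }
  return List::create(_["beta"] = best, _["objective"] = best_obj);
}
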