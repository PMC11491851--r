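// Sparse Bayesian logistic regression with automatic relevance determination.
// Evidence maximization by MacKay fixed-point updates on the per-weight prior
// precisions (alpha_i <- gamma_i / w_i^2, gamma_i = 1 - alpha_i * Sigma_ii)
// around a Laplace approximation at the MAP weights, which are found by a
// damped Newton inner loop. Features whose precision exceeds prune_alpha are
// pruned (weight exactly zero). The intercept keeps a fixed weak prior and is
// never pruned.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double penalised_loglik(const vec &y, const vec &eta, const vec &w,
                               const vec &av) {
  double ll = 0.0;
  for (uword i = 0; i < y.n_elem; ++i) {
    double e = eta(i);
    // log(1 + exp(e)) computed stably
    double lse = (e > 30.0) ? e : std::log1p(std::exp(e));
    ll += y(i) * e - lse;
  }
  return ll - 0.5 * dot(av, square(w));
}

// [[Rcpp::export]]
Rcpp::List ard_logistic_cpp(const arma::mat &X, const arma::vec &y,
                            double prune_alpha, int max_outer, double tol,
                            double intercept_alpha, int max_inner) {
  const uword n = X.n_rows, p = X.n_cols;
  mat X1(n, p + 1);
  X1.col(0).ones();
  if (p > 0) X1.cols(1, p) = X;

  uvec active = regspace<uvec>(0, p);      // 0 = intercept, 1..p = features
  vec alpha(p + 1);
  alpha(0) = intercept_alpha;
  if (p > 0) alpha.subvec(1, p).ones();
  vec w_full(p + 1, fill::zeros);
  bool converged = false;
  int outer = 0;

  while (outer < max_outer) {
    ++outer;
    mat Xa = X1.cols(active);
    vec wa = w_full(active);
    vec av = alpha(active);
    vec eta = Xa * wa;
    double f = penalised_loglik(y, eta, wa, av);
    mat H;

    for (int it = 0; it < max_inner; ++it) {
      vec mu = 1.0 / (1.0 + exp(-eta));
      vec g = Xa.t() * (y - mu) - av % wa;
      vec r = mu % (1.0 - mu);
      H = Xa.t() * (Xa.each_col() % r);
      H.diag() += av;
      vec delta;
      bool ok = solve(delta, H, g, solve_opts::likely_sympd);
      if (!ok) {
        H.diag() += 1e-8;
        delta = solve(H, g);
      }
      double step = 1.0;
      vec w_new, eta_new;
      double f_new;
      for (;;) {
        w_new = wa + step * delta;
        eta_new = Xa * w_new;
        f_new = penalised_loglik(y, eta_new, w_new, av);
        if (f_new >= f - 1e-12 || step < 1e-4) break;
        step *= 0.5;
      }
      double moved = (w_new - wa).is_empty() ? 0.0 : abs(w_new - wa).max();
      wa = w_new;
      eta = eta_new;
      f = f_new;
      if (moved < tol / 10.0) break;
    }

    // Laplace covariance diagonal at the MAP
    mat Sigma;
    if (!inv_sympd(Sigma, H)) Sigma = pinv(H);
    vec sdiag = Sigma.diag();

    vec w_old = w_full;
    w_full.zeros();
    w_full(active) = wa;

    // MacKay update for feature precisions (skip the intercept at index 0)
    std::vector<uword> keep;
    keep.reserve(active.n_elem);
    keep.push_back(0);  // intercept slot always kept (active(0) == 0 always)
    for (uword k = 1; k < active.n_elem; ++k) {
      uword j = active(k);
      double wi = wa(k);
      double gam = 1.0 - alpha(j) * sdiag(k);
      if (gam < 1e-12) gam = 1e-12;
      if (gam > 1.0) gam = 1.0;
      double a_new = (wi * wi < 1e-300) ? std::numeric_limits<double>::infinity()
                                        : gam / (wi * wi);
      alpha(j) = a_new;
      if (a_new > prune_alpha) {
        w_full(j) = 0.0;
      } else {
        keep.push_back(k);
      }
    }
    uvec keep_idx(keep.size());
    for (size_t k = 0; k < keep.size(); ++k) keep_idx(k) = active(keep[k]);
    bool pruned_now = keep_idx.n_elem < active.n_elem;
    active = keep_idx;

    if (!pruned_now && abs(w_full - w_old).max() < tol) {
      converged = true;
      break;
    }
  }

  uvec sel = (active.n_elem > 1) ? active.subvec(1, active.n_elem - 1) - 1
                                 : uvec();
  return Rcpp::List::create(
      Rcpp::Named("weights") = w_full,
      Rcpp::Named("alphas") = alpha,
      Rcpp::Named("selected") = Rcpp::IntegerVector(sel.begin(), sel.end()),
      Rcpp::Named("converged") = converged,
      Rcpp::Named("n_em_iters") = outer);
}
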