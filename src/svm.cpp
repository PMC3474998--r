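// Linear C-SVM on precomputed Gram matrices, solved in the dual by SMO with
// maximal-violating-pair working-set selection. Small problems only (tens to
// low hundreds of trials), which is the regime of ROI beta-series decoding:
// the searchlight scorer below performs O(n_centers * n_trials) fits per
// cross-validation fold, so the solver is deliberately lean.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();
static const double TAU = 1e-12;

struct SvmModel {
  arma::vec alpha;
  double rho;     // decision f(x) = sum_j alpha_j y_j K(x, x_j) - rho
  int iters;
};

// Solve: min_a 0.5 a'Qa - e'a  s.t. 0 <= a <= C, y'a = 0, with Q = (yy') % K.
// Gradient G = Qa - e is maintained incrementally.
static SvmModel smo_solve(const arma::mat& K, const arma::vec& y,
                          double C, double tol, int max_iter) {
  const int n = K.n_rows;
  arma::vec alpha(n, arma::fill::zeros);
  arma::vec G(n, arma::fill::value(-1.0));

  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    // maximal violating pair
    double m = -INF, M = INF;
    int i = -1, j = -1;
    for (int t = 0; t < n; ++t) {
      const double v = -y(t) * G(t);
      const bool up  = (y(t) > 0) ? (alpha(t) < C) : (alpha(t) > 0);
      const bool low = (y(t) > 0) ? (alpha(t) > 0) : (alpha(t) < C);
      if (up  && v > m) { m = v; i = t; }
      if (low && v < M) { M = v; j = t; }
    }
    if (i < 0 || j < 0 || m - M < tol) break;

    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad <= TAU) quad = TAU;

    const double ai_old = alpha(i), aj_old = alpha(j);
    if (y(i) != y(j)) {
      const double delta = (-G(i) - G(j)) / quad;
      const double diff = alpha(i) - alpha(j);
      alpha(i) += delta; alpha(j) += delta;
      if (diff > 0) { if (alpha(j) < 0) { alpha(j) = 0; alpha(i) = diff; } }
      else          { if (alpha(i) < 0) { alpha(i) = 0; alpha(j) = -diff; } }
      if (diff > 0) { if (alpha(i) > C) { alpha(i) = C; alpha(j) = C - diff; } }
      else          { if (alpha(j) > C) { alpha(j) = C; alpha(i) = C + diff; } }
    } else {
      const double delta = (G(i) - G(j)) / quad;
      const double sum = alpha(i) + alpha(j);
      alpha(i) -= delta; alpha(j) += delta;
      if (sum > C) { if (alpha(i) > C) { alpha(i) = C; alpha(j) = sum - C; } }
      else         { if (alpha(j) < 0) { alpha(j) = 0; alpha(i) = sum; } }
      if (sum > C) { if (alpha(j) > C) { alpha(j) = C; alpha(i) = sum - C; } }
      else         { if (alpha(i) < 0) { alpha(i) = 0; alpha(j) = sum; } }
    }

    const double dai = alpha(i) - ai_old, daj = alpha(j) - aj_old;
    if (dai != 0.0 || daj != 0.0)
      G += y % (K.col(i) * (y(i) * dai) + K.col(j) * (y(j) * daj));
  }

  // rho as in libsvm: average y*G over free SVs, else midpoint of bounds
  double ub = INF, lb = -INF, sum_free = 0.0;
  int nr_free = 0;
  for (int t = 0; t < n; ++t) {
    const double yG = y(t) * G(t);
    if (alpha(t) >= C - TAU) {
      if (y(t) < 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (alpha(t) <= TAU) {
      if (y(t) > 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else { ++nr_free; sum_free += yG; }
  }
  double rho;
  if (nr_free > 0) rho = sum_free / nr_free;
  else if (std::isfinite(ub) && std::isfinite(lb)) rho = (ub + lb) / 2.0;
  else rho = 0.0;

  SvmModel mod; mod.alpha = alpha; mod.rho = rho; mod.iters = it;
  return mod;
}

// [[Rcpp::export(name = ".svm_fit_gram")]]
List svm_fit_gram(const arma::mat& K, const arma::vec& y,
                  double C, double tol, int max_iter) {
  SvmModel mod = smo_solve(K, y, C, tol, max_iter);
  arma::vec f = K * (mod.alpha % y) - mod.rho;
  return List::create(_["alpha"] = mod.alpha,
                      _["rho"] = mod.rho,
                      _["iters"] = mod.iters,
                      _["decision"] = f);
}

// decision values for test rows given K_test_train (n_test x n_train)
// [[Rcpp::export(name = ".svm_decision_gram")]]
arma::vec svm_decision_gram(const arma::mat& Ktt, const arma::vec& alpha,
                            const arma::vec& y, double rho) {
  return Ktt * (alpha % y) - rho;
}

// Leave-one-out predictions (+1/-1) on a Gram matrix; each fold refits from
// scratch. Ties in the decision value resolve to +1 (documented tie-break).
static arma::ivec loo_predict(const arma::mat& K, const arma::vec& y,
                              double C, double tol, int max_iter) {
  const int n = K.n_rows;
  arma::ivec pred(n);
  arma::uvec all = arma::regspace<arma::uvec>(0, n - 1);
  for (int t = 0; t < n; ++t) {
    arma::uvec tr = all.elem(arma::find(all != (unsigned) t));
    arma::mat Kr = K.submat(tr, tr);
    arma::vec yr = y.elem(tr);
    SvmModel mod = smo_solve(Kr, yr, C, tol, max_iter);
    arma::vec kt = K.row(t).t();
    double f = arma::dot(kt.elem(tr), mod.alpha % yr) - mod.rho;
    pred(t) = (f >= 0) ? 1 : -1;
  }
  return pred;
}

// [[Rcpp::export(name = ".svm_loo_gram")]]
arma::ivec svm_loo_gram(const arma::mat& K, const arma::vec& y,
                        double C, double tol, int max_iter) {
  return loo_predict(K, y, C, tol, max_iter);
}

// Searchlight scorer: for every center voxel, the LOO cross-validated SVM
// accuracy over its neighborhood's features, computed within X only.
// X: n_trials x n_voxels betas; nb: list of 1-based column index vectors.
// [[Rcpp::export(name = ".searchlight_loo_scores")]]
arma::vec searchlight_loo_scores(const arma::mat& X, const List& nb,
                                 const arma::vec& y, double C, double tol,
                                 int max_iter) {
  const int n_centers = nb.size();
  const int n = X.n_rows;
  arma::vec scores(n_centers);
  for (int c = 0; c < n_centers; ++c) {
    IntegerVector idx1 = nb[c];
    arma::uvec idx(idx1.size());
    for (int k = 0; k < idx1.size(); ++k) idx(k) = (unsigned)(idx1[k] - 1);
    arma::mat Xc = X.cols(idx);
    arma::mat K = Xc * Xc.t();
    arma::ivec pred = loo_predict(K, y, C, tol, max_iter);
    int correct = 0;
    for (int t = 0; t < n; ++t)
      if ((pred(t) > 0 && y(t) > 0) || (pred(t) < 0 && y(t) < 0)) ++correct;
    scores(c) = (double) correct / (double) n;
  }
  return scores;
}
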