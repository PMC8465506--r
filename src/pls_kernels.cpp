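// NIPALS PLS1 and its leave-one-out cross-validation kernel.
// PLS1 with a single response needs no inner iteration: each weight
// vector is obtained in closed form from the deflated X and y.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Extract up to nlv latent variables from (already centered) Xc, yc.
// Returns the number actually extracted (may stop early on rank loss).
static int nipals_pls1(const mat& Xc, const vec& yc, int nlv,
                       mat& W, mat& P, vec& q, mat* T = nullptr) {
  mat X = Xc;
  vec y = yc;
  const double tol = 1e-12 * std::max(1.0, norm(yc));
  int a = 0;
  for (; a < nlv; ++a) {
    vec w = X.t() * y;
    double nw = norm(w);
    if (nw < tol || !std::isfinite(nw)) break;
    w /= nw;
    vec t = X * w;
    double tt = dot(t, t);
    if (tt < 1e-30) break;
    vec p = X.t() * t / tt;
    double qa = dot(y, t) / tt;
    W.col(a) = w;
    P.col(a) = p;
    q(a) = qa;
    if (T) T->col(a) = t;
    X -= t * p.t();
    y -= qa * t;
  }
  return a;
}

// Cumulative regression vectors: column k-1 gives coefficients of the
// k-latent-variable model, B_k = W_k (P_k' W_k)^{-1} q_k.
static mat coef_path(const mat& W, const mat& P, const vec& q, int nlv) {
  mat B(W.n_rows, nlv);
  for (int k = 1; k <= nlv; ++k) {
    mat Wk = W.cols(0, k - 1);
    mat Pk = P.cols(0, k - 1);
    vec bk = Wk * solve(Pk.t() * Wk, q.subvec(0, k - 1));
    B.col(k - 1) = bk;
  }
  return B;
}

// [[Rcpp::export]]
Rcpp::List cpp_pls1(const arma::mat& X, const arma::vec& y, int nlv) {
  rowvec x_mean = mean(X, 0);
  double y_mean = mean(y);
  mat Xc = X.each_row() - x_mean;
  vec yc = y - y_mean;
  mat W(X.n_cols, nlv, fill::zeros), P(X.n_cols, nlv, fill::zeros);
  vec q(nlv, fill::zeros);
  mat T(X.n_rows, nlv, fill::zeros);
  int got = nipals_pls1(Xc, yc, nlv, W, P, q, &T);
  if (got == 0) Rcpp::stop("no latent variable could be extracted (rank-0 predictor matrix)");
  W = W.cols(0, got - 1);
  P = P.cols(0, got - 1);
  q = q.subvec(0, got - 1);
  mat B = coef_path(W, P, q, got);
  mat scores = T.cols(0, got - 1);  // deflation-stage scores, mutually orthogonal
  return Rcpp::List::create(
    Rcpp::Named("n_lv") = got,
    Rcpp::Named("x_mean") = x_mean.t(),
    Rcpp::Named("y_mean") = y_mean,
    Rcpp::Named("weights") = W,
    Rcpp::Named("x_loadings") = P,
    Rcpp::Named("y_loadings") = q,
    Rcpp::Named("coef_path") = B,
    Rcpp::Named("scores") = scores);
}

// Leave-one-out predictions for 1..max_lv latent variables.
// Each fold re-centers X and y on the retained samples before fitting,
// so no information from the held-out sample enters the fold model.
// When a fold runs out of rank before max_lv, the deepest attainable
// model is carried forward for the remaining columns.
// [[Rcpp::export]]
arma::mat cpp_loo_pred(const arma::mat& X, const arma::vec& y, int max_lv) {
  const int n = X.n_rows, p = X.n_cols;
  mat out(n, max_lv);
  mat W(p, max_lv), P(p, max_lv);
  vec q(max_lv);
  for (int i = 0; i < n; ++i) {
    mat Xi = X;
    Xi.shed_row(i);
    vec yi = y;
    yi.shed_row(i);
    rowvec xm = mean(Xi, 0);
    double ym = mean(yi);
    mat Xc = Xi.each_row() - xm;
    vec yc = yi - ym;
    W.zeros(); P.zeros(); q.zeros();
    int got = nipals_pls1(Xc, yc, max_lv, W, P, q);
    // sequential-deflation prediction of the held-out spectrum
    vec xc = (X.row(i) - xm).t();
    double yhat = ym;
    for (int a = 0; a < max_lv; ++a) {
      if (a < got) {
        double t = dot(xc, W.col(a));
        xc -= t * P.col(a);
        yhat += t * q(a);
      }
      out(i, a) = yhat;
    }
  }
  return out;
}

// RMSECV over all interval combinations: for each combination the member
// intervals' columns are concatenated and LOO RMSECV is computed for
// 1..max_lv latent variables. combos is a list of 0-based column index
// vectors. Returns a (n_combos x max_lv) matrix of RMSECV values.
// [[Rcpp::export]]
arma::mat cpp_combo_rmsecv(const arma::mat& X, const arma::vec& y,
                           const Rcpp::List& combos, int max_lv) {
  const int nc = combos.size();
  const int n = X.n_rows;
  mat out(nc, max_lv);
  for (int c = 0; c < nc; ++c) {
    uvec cols = Rcpp::as<uvec>(combos[c]);
    mat Xs = X.cols(cols);
    int lv = std::min<int>(max_lv, std::min<int>(n - 2, (int)Xs.n_cols));
    mat pred = cpp_loo_pred(Xs, y, lv);
    for (int k = 0; k < max_lv; ++k) {
      int kk = std::min(k, lv - 1);
      out(c, k) = std::sqrt(accu(square(pred.col(kk) - y)) / n);
    }
  }
  return out;
}
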