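#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Multiplicative-update NMF under the Euclidean cost J = ||A - W*H||_F.
// After every iteration each column of W is rescaled to unit L2 norm and the
// matching row of H is scaled by the inverse factor, so the product W*H is
// unchanged by the normalization. With fix_w = true only the H update runs
// (activation estimation against a fixed synergy pattern matrix).
//
// Denominators are guarded by a small constant so that zero rows/columns do
// not produce NaNs; guarded updates remain non-increasing in J to numerical
// precision. Iterations stop when the relative decrease of J over one
// iteration falls below tol, or at max_iter.
// [[Rcpp::export]]
Rcpp::List nmf_mu_cpp(const arma::mat& A, arma::mat W, arma::mat H,
                      int max_iter, double tol, bool fix_w) {
  const double eps = 1e-12;
  std::vector<double> cost;
  cost.reserve(64);
  mat WtA, WtW, AHt, HHt, R;
  R = A - W * H;
  double j_prev = norm(R, "fro");
  cost.push_back(j_prev);
  int iters = 0;
  for (int it = 0; it < max_iter; ++it) {
    WtA = W.t() * A;
    WtW = W.t() * W;
    H %= WtA / (WtW * H + eps);
    if (!fix_w) {
      AHt = A * H.t();
      HHt = H * H.t();
      W %= AHt / (W * HHt + eps);
      for (uword j = 0; j < W.n_cols; ++j) {
        double nj = norm(W.col(j), 2);
        if (nj > eps) {
          W.col(j) /= nj;
          H.row(j) *= nj;
        }
      }
    }
    R = A - W * H;
    double j_cur = norm(R, "fro");
    cost.push_back(j_cur);
    iters = it + 1;
    double rel = (j_prev - j_cur) / std::max(j_prev, eps);
    j_prev = j_cur;
    if (rel < tol) break;
  }
  return Rcpp::List::create(
    Rcpp::Named("W") = W,
    Rcpp::Named("H") = H,
    Rcpp::Named("cost") = cost,
    Rcpp::Named("iterations") = iters);
}
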