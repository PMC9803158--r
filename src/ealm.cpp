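// Exact augmented Lagrange multiplier iterations for the robust-PCA split
// X = A + E (nuclear norm + weighted l1).  The inner A/E alternation needs
// one singular value shrinkage per pass; on the strongly rectangular
// trajectory matrices this package feeds it, the SVD is taken through the
// eigendecomposition of the small-side Gram matrix (exact up to the usual
// sqrt(eps) floor on tiny singular values, which sit far below every
// shrinkage threshold the loop uses).

#include <RcppArmadillo.h>

using namespace Rcpp;

static double soft1(double v, double tau) {
  double a = std::fabs(v) - tau;
  return a > 0 ? (v > 0 ? a : -a) : 0.0;
}

// A <- U (Sigma - tau)_+ V^T for M = U Sigma V^T, via the Gram matrix of
// the smaller side.  Returns the surviving singular values in sv_keep.
static void sv_shrink(const arma::mat& M, double tau, arma::mat& A,
                      arma::vec& sv_keep) {
  const bool wide = M.n_rows <= M.n_cols;
  arma::mat G;                                  // p x p, p = min dim
  if (wide) G = M * M.t(); else G = M.t() * M;
  arma::vec ev;
  arma::mat U;
  arma::eig_sym(ev, U, G);                      // ascending
  arma::vec sv = arma::sqrt(arma::clamp(ev, 0.0, arma::datum::inf));
  arma::uvec keep = arma::find(sv > tau);
  if (keep.n_elem == 0) {
    A.zeros(M.n_rows, M.n_cols);
    sv_keep.reset();
    return;
  }
  arma::mat Uk = U.cols(keep);
  arma::vec svk = sv(keep);
  // W = Uk diag((sv - tau)/sv) Uk^T applied to M from the small side
  arma::mat W = Uk * arma::diagmat((svk - tau) / svk) * Uk.t();
  A = wide ? W * M : M * W;
  sv_keep = arma::sort(svk - tau, "descend");
}

// [[Rcpp::export(name = ".ealm_c")]]
List ealm_c(const arma::mat& X, const arma::mat& Y0, double eta, double mu0,
            double rho, double tol, int max_outer, double inner_tol,
            int max_inner, bool record_lagrangian) {
  const arma::uword m = X.n_rows, n = X.n_cols;
  const double norm_x = arma::norm(X, "fro");
  arma::mat A(m, n, arma::fill::zeros), E(m, n, arma::fill::zeros), Y = Y0;
  double mu = mu0;
  arma::vec sv_keep;
  std::vector<double> lag_vals, lag_outer, res_trace;
  double res = 1.0;
  int outer = 0;
  bool converged = false;
  arma::mat A_old, E_old, G, R;
  for (outer = 1; outer <= max_outer; ++outer) {
    double change_ref = std::max(arma::norm(A, "fro") + arma::norm(E, "fro"),
                                 norm_x);
    for (int inner = 0; inner < max_inner; ++inner) {
      A_old = A; E_old = E;
      sv_shrink(X - E + Y / mu, 1.0 / mu, A, sv_keep);
      G = X - A + Y / mu;
      E = G;
      double te = eta / mu;
      E.transform([te](double v) { return soft1(v, te); });
      if (record_lagrangian) {
        R = X - A - E;
        double lag = arma::accu(sv_keep) + eta * arma::accu(arma::abs(E)) +
                     arma::accu(Y % R) + 0.5 * mu * arma::accu(R % R);
        lag_vals.push_back(lag);
        lag_outer.push_back((double)outer);
      }
      double change = (arma::norm(A - A_old, "fro") +
                       arma::norm(E - E_old, "fro")) / change_ref;
      if (change < inner_tol) break;
    }
    R = X - A - E;
    Y += mu * R;
    mu *= rho;
    res = arma::norm(R, "fro") / norm_x;
    res_trace.push_back(res);
    if (res <= tol) { converged = true; break; }
  }
  // numerical rank of A from the singular values of the last shrinkage
  double s_tol = sv_keep.n_elem > 0
    ? sv_keep.max() * std::max(m, n) * std::numeric_limits<double>::epsilon() * 10.0
    : 0.0;
  int s = sv_keep.n_elem > 0 ? (int)arma::sum(sv_keep > s_tol) : 0;
  return List::create(
    _["A"] = A, _["E"] = E, _["s"] = s,
    _["iterations"] = std::min(outer, max_outer),
    _["final_residual"] = res, _["converged"] = converged,
    _["residual_trace"] = res_trace,
    _["lagrangian"] = lag_vals, _["lagrangian_outer"] = lag_outer);
}

// Series of the elementary components lambda_i u_i v_i^T by diagonal
// averaging, computed as scaled convolutions of the singular vector pairs
// (the anti-diagonal sums of a rank-1 matrix are the open convolution of
// its factors).
// [[Rcpp::export(name = ".component_series_c")]]
arma::mat component_series_c(const arma::mat& U, const arma::mat& V,
                             const arma::vec& lambda) {
  const int L = U.n_rows, K = V.n_rows, N = L + K - 1;
  const int s = lambda.n_elem;
  arma::mat Z(N, s, arma::fill::zeros);
  for (int c = 0; c < s; ++c) {
    for (int i = 0; i < L; ++i) {
      const double ui = lambda[c] * U(i, c);
      for (int j = 0; j < K; ++j) Z(i + j, c) += ui * V(j, c);
    }
  }
  for (int k = 0; k < N; ++k) {
    double cnt = std::min(std::min(k + 1, N - k), std::min(L, K));
    Z.row(k) /= cnt;
  }
  return Z;
}
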