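// Empirical mode decomposition (sifting with natural cubic spline envelopes)
// and its noise-assisted ensemble variant.  Kept in C++ because the pipeline
// runs a full EEMD (typically 100 ensemble members) inside every analysis
// window; all workspace is preallocated once per ensemble.

#include <RcppArmadillo.h>

using namespace Rcpp;

struct EmdWork {
  std::vector<int> imax, imin;
  std::vector<double> t, y;                 // extended envelope knots
  std::vector<double> h2, alpha, l, mu, z, M;  // spline workspace
  std::vector<double> env_u, env_l;
  std::vector<double> h, h_new, r;
  explicit EmdWork(int n) : env_u(n), env_l(n), h(n), h_new(n), r(n) {
    imax.reserve(n); imin.reserve(n);
    t.reserve(n + 2); y.reserve(n + 2);
    h2.reserve(n + 2); alpha.reserve(n + 2); l.reserve(n + 2);
    mu.reserve(n + 2); z.reserve(n + 2); M.reserve(n + 2);
  }
};

// Locate strict local extrema; plateaus contribute their left edge.
// Sign-of-difference method: zero differences inherit the previous sign.
static void find_extrema(const std::vector<double>& x, int n,
                         std::vector<int>& imax, std::vector<int>& imin) {
  imax.clear(); imin.clear();
  int prev_sign = 0, plateau_start = 0;
  for (int i = 0; i < n - 1; ++i) {
    double d = x[i + 1] - x[i];
    int s = (d > 0) - (d < 0);
    if (s == 0) continue;
    if (prev_sign > 0 && s < 0) imax.push_back(plateau_start);
    if (prev_sign < 0 && s > 0) imin.push_back(plateau_start);
    prev_sign = s;
    plateau_start = i + 1;
  }
}

// Mirror the outermost extremum of each kind beyond the series ends so the
// envelope spline spans the full support.
static void extend_knots(const std::vector<int>& idx,
                         const std::vector<double>& x, int n,
                         std::vector<double>& t, std::vector<double>& y) {
  t.clear(); y.clear();
  const int k = (int)idx.size();
  if (idx[0] > 0) { t.push_back(-(double)idx[0]); y.push_back(x[idx[0]]); }
  for (int i = 0; i < k; ++i) {
    t.push_back((double)idx[i]);
    y.push_back(x[idx[i]]);
  }
  if (idx[k - 1] < n - 1) {
    t.push_back(2.0 * (n - 1) - idx[k - 1]);
    y.push_back(x[idx[k - 1]]);
  }
}

// Natural cubic spline through (t, y), evaluated at 0..n-1 into out.
static void spline_envelope(EmdWork& w, int n, std::vector<double>& out) {
  const std::vector<double>& t = w.t;
  const std::vector<double>& y = w.y;
  const int m = (int)t.size();
  if (m == 2) {
    double slope = (y[1] - y[0]) / (t[1] - t[0]);
    for (int q = 0; q < n; ++q) out[q] = y[0] + slope * (q - t[0]);
    return;
  }
  std::vector<double>& h = w.h2; std::vector<double>& alpha = w.alpha;
  std::vector<double>& l = w.l; std::vector<double>& mu = w.mu;
  std::vector<double>& z = w.z; std::vector<double>& M = w.M;
  h.resize(m - 1); alpha.resize(m); l.resize(m); mu.resize(m); z.resize(m);
  M.resize(m);
  for (int i = 0; i < m - 1; ++i) h[i] = t[i + 1] - t[i];
  for (int i = 1; i < m - 1; ++i)
    alpha[i] = 3.0 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1]);
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int i = 1; i < m - 1; ++i) {
    l[i] = 2.0 * (t[i + 1] - t[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l[i];
    z[i] = (alpha[i] - h[i - 1] * z[i - 1]) / l[i];
  }
  M[m - 1] = 0.0;
  for (int i = m - 2; i >= 0; --i) M[i] = z[i] - mu[i] * M[i + 1];
  int seg = 0;
  for (int q = 0; q < n; ++q) {
    while (seg < m - 2 && t[seg + 1] < q) ++seg;
    double hi = h[seg];
    double b = (y[seg + 1] - y[seg]) / hi -
               hi * (2.0 * M[seg] + M[seg + 1]) / 3.0;
    double d = (M[seg + 1] - M[seg]) / (3.0 * hi);
    double dx = q - t[seg];
    out[q] = y[seg] + dx * (b + dx * (M[seg] + dx * d));
  }
}

// One EMD of x (length n) into at most max_imf IMFs stored as columns of
// imfs (preallocated n x max_imf); the residual stays in w.r.  Sifting
// stops on the sum-of-squares ("standard deviation") criterion or after
// max_sift passes.
static int emd_core(const double* x, int n, int max_imf, double sd_tol,
                    int max_sift, EmdWork& w, arma::mat& imfs) {
  std::copy(x, x + n, w.r.begin());
  int n_imf = 0;
  for (int k = 0; k < max_imf; ++k) {
    find_extrema(w.r, n, w.imax, w.imin);
    if (w.imax.empty() || w.imin.empty() ||
        (int)(w.imax.size() + w.imin.size()) < 2)
      break;
    w.h = w.r;
    for (int s = 0; s < max_sift; ++s) {
      find_extrema(w.h, n, w.imax, w.imin);
      if (w.imax.empty() || w.imin.empty()) break;
      extend_knots(w.imax, w.h, n, w.t, w.y);
      if (w.t.size() < 2) break;
      spline_envelope(w, n, w.env_u);
      extend_knots(w.imin, w.h, n, w.t, w.y);
      if (w.t.size() < 2) break;
      spline_envelope(w, n, w.env_l);
      double num = 0.0, den = 1e-300;
      for (int q = 0; q < n; ++q) {
        double m_env = 0.5 * (w.env_u[q] + w.env_l[q]);
        num += m_env * m_env;
        den += w.h[q] * w.h[q];
        w.h_new[q] = w.h[q] - m_env;
      }
      w.h.swap(w.h_new);
      if (num / den < sd_tol) break;
    }
    for (int q = 0; q < n; ++q) {
      imfs(q, k) = w.h[q];
      w.r[q] -= w.h[q];
    }
    ++n_imf;
  }
  return n_imf;
}

// [[Rcpp::export(name = ".emd_c")]]
List emd_c(const arma::vec& x, int max_imf, double sd_tol, int max_sift) {
  const int n = x.n_elem;
  EmdWork w(n);
  arma::mat imfs(n, max_imf, arma::fill::zeros);
  int n_imf = emd_core(x.memptr(), n, max_imf, sd_tol, max_sift, w, imfs);
  return List::create(
    _["imfs"] = imfs.cols(0, std::max(n_imf, 1) - 1),
    _["n_imf"] = n_imf,
    _["residual"] = arma::vec(w.r));
}

// Ensemble EMD: noise columns are generated by the caller (R's RNG keeps
// the whole pipeline reproducible from one seed).  IMFs are averaged by
// index; members that stop early contribute zeros for missing indices.
// [[Rcpp::export(name = ".eemd_c")]]
List eemd_c(const arma::vec& x, const arma::mat& noise, int max_imf,
            double sd_tol, int max_sift) {
  const int n = x.n_elem;
  const int ens = noise.n_cols;
  EmdWork w(n);
  arma::mat acc(n, max_imf, arma::fill::zeros);
  arma::mat imfs(n, max_imf, arma::fill::zeros);
  arma::vec resid_acc(n, arma::fill::zeros);
  arma::vec xe(n);
  int n_imf_max = 0;
  for (int e = 0; e < ens; ++e) {
    xe = x + noise.col(e);
    imfs.zeros();
    int n_imf = emd_core(xe.memptr(), n, max_imf, sd_tol, max_sift, w, imfs);
    if (n_imf > 0) acc.cols(0, n_imf - 1) += imfs.cols(0, n_imf - 1);
    for (int q = 0; q < n; ++q) resid_acc[q] += w.r[q];
    if (n_imf > n_imf_max) n_imf_max = n_imf;
  }
  acc /= (double)ens;
  resid_acc /= (double)ens;
  return List::create(
    _["imfs"] = n_imf_max > 0 ? acc.cols(0, n_imf_max - 1)
                              : arma::mat(n, 0),
    _["n_imf"] = n_imf_max,
    _["residual"] = resid_acc);
}

// Biased normalized sample autocorrelation: divisor N and the lag-0
// autocovariance, so P(0) == 1 bit-exactly.
// [[Rcpp::export(name = ".autocorr_c")]]
arma::vec autocorr_c(const arma::vec& z, int max_lag) {
  const int n = z.n_elem;
  arma::vec a = z - arma::mean(z);
  // accumulate the normalizer in the same order as the lag-k sums so that
  // P(0) is the quotient of two identical sums
  double s0 = 0.0;
  for (int t = 0; t < n; ++t) s0 += a[t] * a[t];
  arma::vec p(max_lag + 1);
  for (int k = 0; k <= max_lag; ++k) {
    double s = 0.0;
    for (int t = 0; t + k < n; ++t) s += a[t] * a[t + k];
    p[k] = s / s0;
  }
  return p;
}
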