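#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static bool mvee_core(const arma::mat& X, double tol, int max_iter,
                      arma::vec& center, arma::mat& A, int& iters);

// Minimum-volume enclosing ellipsoid of the rows of X (n x d): Khachiyan's
// barycentric coordinate ascent with Todd-Yildirim away steps (the
// drop-weight variant, which converges linearly instead of sublinearly).
// Returns center c and shape matrix A with (x - c)' A (x - c) <= 1 for
// every row, to relative tolerance `tol` on the duality gap.
// [[Rcpp::export]]
List khachiyan_mvee(const arma::mat& X, double tol = 1e-7,
                    int max_iter = 200000) {
  arma::vec center;
  arma::mat A;
  int iters = 0;
  bool converged = mvee_core(X, tol, max_iter, center, A, iters);
  return List::create(_["center"] = center, _["A"] = A,
                      _["iterations"] = iters, _["converged"] = converged);
}

static bool mvee_core(const arma::mat& X, double tol, int max_iter,
                      arma::vec& center, arma::mat& A, int& iters) {
  const int n = X.n_rows;
  const int d = X.n_cols;
  if (n < d + 1) stop("khachiyan_mvee: need at least d + 1 points");

  arma::mat Q(d + 1, n);
  Q.rows(0, d - 1) = X.t();
  Q.row(d).ones();

  arma::vec u(n);
  u.fill(1.0 / n);

  bool converged = false;
  int it = 0;
  arma::vec M(n);
  while (it < max_iter) {
    arma::mat V = Q * arma::diagmat(u) * Q.t();
    arma::mat invV;
    if (!arma::inv_sympd(invV, V)) {
      if (!arma::pinv(invV, V)) stop("khachiyan_mvee: singular weight matrix");
    }
    M = arma::sum((invV * Q) % Q, 0).t();

    arma::uword j_add;
    const double m_add = M.max(j_add);
    const double e_add = m_add / (d + 1.0) - 1.0;

    // worst point among the current support (candidates for weight removal)
    arma::uword j_rem = j_add;
    double m_rem = arma::datum::inf;
    for (int i = 0; i < n; ++i) {
      if (u(i) > 1e-12 && M(i) < m_rem) { m_rem = M(i); j_rem = i; }
    }
    const double e_rem = 1.0 - m_rem / (d + 1.0);

    if (std::max(e_add, e_rem) < tol) { converged = true; break; }

    arma::uword j;
    double step;
    if (e_add >= e_rem) {
      j = j_add;
      step = (m_add - d - 1.0) / ((d + 1.0) * (m_add - 1.0));
    } else {
      j = j_rem;
      step = (m_rem - d - 1.0) / ((d + 1.0) * (m_rem - 1.0));
      const double cap = -u(j) / (1.0 - u(j));
      if (step < cap) step = cap;
    }
    u *= (1.0 - step);
    u(j) += step;
    ++it;
  }

  arma::rowvec c = u.t() * X;
  arma::mat P = X.t() * arma::diagmat(u) * X - c.t() * c;
  if (!arma::inv_sympd(A, P)) {
    if (!arma::pinv(A, P)) stop("khachiyan_mvee: degenerate point set");
  }
  A /= d;
  center = arma::vec(c.t());
  iters = it;
  return converged;
}

// volume (up to the dimension constant) of the tight enclosing ellipsoid
// implied by (center, A): cutoff = max Mahalanobis^2 under Sigma = A^-1
static double subset_volume(const arma::mat& Xs, const arma::vec& center,
                            const arma::mat& A) {
  const int d = Xs.n_cols;
  arma::mat diff = Xs.each_row() - center.t();
  arma::vec m2 = arma::sum((diff * A) % diff, 1);
  const double cutoff = m2.max();  // A-metric: inside <=> m2 <= cutoff ~ 1
  double logdetA, sign;
  arma::log_det(logdetA, sign, A);
  // vol ~ sqrt(det(A^-1)) * cutoff^(d/2)
  return std::exp(-0.5 * logdetA) * std::pow(cutoff, d / 2.0);
}

// Exhaustive search for the minimum-volume ellipsoid covering exactly m of
// the n points: fits the exact enclosing ellipsoid of every m-subset and
// returns the 1-based indices of the best one. Only sensible when
// choose(n, m) is small.
// [[Rcpp::export]]
IntegerVector mvee_best_subset(const arma::mat& X, int m, double tol = 1e-7,
                               int max_iter = 200000) {
  const int n = X.n_rows;
  const int d = X.n_cols;
  if (m < d + 1 || m > n) stop("mvee_best_subset: need d + 1 <= m <= n");
  std::vector<int> comb(m);
  for (int i = 0; i < m; ++i) comb[i] = i;
  std::vector<int> best;
  double best_vol = R_PosInf;
  arma::uvec idx(m);
  while (true) {
    for (int i = 0; i < m; ++i) idx(i) = comb[i];
    arma::mat Xs = X.rows(idx);
    arma::vec center;
    arma::mat A;
    int iters = 0;
    bool ok = true;
    double vol = R_PosInf;
    try {
      mvee_core(Xs, tol, max_iter, center, A, iters);
      vol = subset_volume(Xs, center, A);
    } catch (...) { ok = false; }
    if (ok && vol < best_vol) { best_vol = vol; best = comb; }
    // next combination
    int i = m - 1;
    while (i >= 0 && comb[i] == n - m + i) --i;
    if (i < 0) break;
    ++comb[i];
    for (int j = i + 1; j < m; ++j) comb[j] = comb[j - 1] + 1;
  }
  IntegerVector out(best.size());
  for (size_t i = 0; i < best.size(); ++i) out[i] = best[i] + 1;
  return out;
}
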