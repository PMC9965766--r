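// PCLRC inner loop: repeated subsampling -> Spearman correlation ->
// CLR background filtering on squared correlations -> retention of the
// top-quantile edges -> keep counts. Kept in C++ because the differential
// connectivity permutation test reruns this hundreds of times.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Average ranks (ties.method = "average") of one column.
static arma::vec avg_ranks(const arma::vec& x) {
  const arma::uword n = x.n_elem;
  arma::uvec ord = arma::sort_index(x);
  arma::vec r(n);
  arma::uword i = 0;
  while (i < n) {
    arma::uword j = i;
    while (j + 1 < n && x(ord(j + 1)) == x(ord(i))) ++j;
    double avg = 0.5 * (static_cast<double>(i) + static_cast<double>(j)) + 1.0;
    for (arma::uword k = i; k <= j; ++k) r(ord(k)) = avg;
    i = j + 1;
  }
  return r;
}

// Column-standardised rank matrix; zero-variance columns become all-zero
// so their correlations are 0 rather than NaN.
static arma::mat rank_standardise(const arma::mat& X) {
  arma::mat Z(X.n_rows, X.n_cols);
  const double n = static_cast<double>(X.n_rows);
  for (arma::uword j = 0; j < X.n_cols; ++j) {
    arma::vec r = avg_ranks(X.col(j));
    double mu = arma::mean(r);
    double sd = arma::stddev(r);
    if (sd > 0) {
      Z.col(j) = (r - mu) / (sd * std::sqrt(n - 1.0));
    } else {
      Z.col(j).zeros();
    }
  }
  return Z;
}

// [[Rcpp::export]]
arma::mat cpp_spearman(const arma::mat& X) {
  arma::mat Z = rank_standardise(X);
  arma::mat R = Z.t() * Z;
  R.diag().ones();
  return R;
}

// CLR scores of a symmetric non-negative association matrix:
// z_{i|j} = (M_ij - mean(M_i.)) / sd(M_i.) over row i excluding the
// diagonal; clr_ij = sqrt(max(0, z_{i|j})^2 + max(0, z_{j|i})^2).
// [[Rcpp::export]]
arma::mat cpp_clr(const arma::mat& M) {
  const arma::uword p = M.n_rows;
  arma::vec mu(p), sd(p);
  for (arma::uword i = 0; i < p; ++i) {
    arma::vec row(p - 1);
    arma::uword k = 0;
    for (arma::uword j = 0; j < p; ++j) if (j != i) row(k++) = M(i, j);
    mu(i) = arma::mean(row);
    sd(i) = (p > 2) ? arma::stddev(row) : 0.0;
  }
  arma::mat out(p, p, arma::fill::zeros);
  for (arma::uword i = 0; i < p; ++i) {
    for (arma::uword j = i + 1; j < p; ++j) {
      double zi = (sd(i) > 0) ? std::max(0.0, (M(i, j) - mu(i)) / sd(i)) : 0.0;
      double zj = (sd(j) > 0) ? std::max(0.0, (M(j, i) - mu(j)) / sd(j)) : 0.0;
      double v = std::sqrt(zi * zi + zj * zj);
      out(i, j) = v;
      out(j, i) = v;
    }
  }
  return out;
}

// Indicator of the top `retention` fraction of the strictly positive CLR
// scores (upper triangle); ties at the cutoff are all kept.
static arma::mat top_quantile_mask(const arma::mat& clr, double retention) {
  const arma::uword p = clr.n_rows;
  std::vector<double> vals;
  vals.reserve(p * (p - 1) / 2);
  for (arma::uword i = 0; i < p; ++i)
    for (arma::uword j = i + 1; j < p; ++j)
      if (clr(i, j) > 0) vals.push_back(clr(i, j));
  arma::mat mask(p, p, arma::fill::zeros);
  if (vals.empty()) return mask;
  arma::uword keep = static_cast<arma::uword>(std::ceil(retention * vals.size()));
  if (keep == 0) return mask;
  if (keep > vals.size()) keep = vals.size();
  std::nth_element(vals.begin(), vals.begin() + (keep - 1), vals.end(),
                   std::greater<double>());
  double cutoff = vals[keep - 1];
  for (arma::uword i = 0; i < p; ++i)
    for (arma::uword j = i + 1; j < p; ++j)
      if (clr(i, j) >= cutoff && clr(i, j) > 0) {
        mask(i, j) = 1.0;
        mask(j, i) = 1.0;
      }
  return mask;
}

// subsets: one column per iteration of 1-based row indices into X.
// [[Rcpp::export]]
arma::mat cpp_pclrc_counts(const arma::mat& X, const arma::umat& subsets,
                           double retention) {
  const arma::uword p = X.n_cols;
  arma::mat counts(p, p, arma::fill::zeros);
  for (arma::uword it = 0; it < subsets.n_cols; ++it) {
    arma::uvec idx = subsets.col(it) - 1;
    arma::mat R = cpp_spearman(X.rows(idx));
    arma::mat M = arma::square(R);
    M.diag().zeros();
    counts += top_quantile_mask(cpp_clr(M), retention);
  }
  return counts;
}
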