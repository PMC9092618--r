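// Exhaustive best-subset enumeration kernel.
//
// Fits every size-k subset of the descriptor pool by ordinary least squares
// (intercept included) on the training rows, using precomputed Gram-matrix
// blocks, and scores each subset by trimmed mean absolute error on a held-out
// validation set. Trimming drops the ceil-rounded 5% (configurable) largest
// absolute errors before the mean/SD, matching the MAE-based model-quality
// criteria used for ranking.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export(name = ".enum_subsets_cpp")]]
List enum_subsets_cpp(const arma::mat& Xtr, const arma::vec& ytr,
                      const arma::mat& Xval, const arma::vec& yval,
                      const int k, const double trim_frac) {
  const int p = Xtr.n_cols;
  const int ntr = Xtr.n_rows;
  const int nval = Xval.n_rows;
  if (k < 1 || k > p) stop("subset size out of range");

  // augmented design [1, X]; Gram blocks computed once
  arma::mat A(ntr, p + 1);
  A.col(0).ones();
  A.cols(1, p) = Xtr;
  const arma::mat G = A.t() * A;
  const arma::vec g = A.t() * ytr;
  const double yty = arma::dot(ytr, ytr);
  const double sst = yty - ntr * std::pow(arma::mean(ytr), 2);

  // number of combinations C(p, k)
  double ncomb = 1.0;
  for (int i = 0; i < k; ++i) ncomb = ncomb * (p - i) / (i + 1);
  const R_xlen_t C = (R_xlen_t) std::llround(ncomb);

  IntegerMatrix combos(k, C);
  NumericVector mae(C), sd_trim(C), r2(C);

  const int ndrop = (int) std::floor(trim_frac * nval + 0.5); // round half up
  const int nkeep = nval - ndrop;
  if (nkeep < 1) stop("trimming removes all validation points");

  std::vector<int> idx(k);
  for (int i = 0; i < k; ++i) idx[i] = i;

  arma::uvec sel(k + 1);
  arma::vec abserr(nval);

  for (R_xlen_t c = 0;; ++c) {
    sel(0) = 0;
    for (int i = 0; i < k; ++i) sel(i + 1) = idx[i] + 1;

    const arma::mat Gs = G.submat(sel, sel);
    const arma::vec gs = g.elem(sel);
    arma::vec beta;
    bool ok = arma::solve(beta, Gs, gs, arma::solve_opts::no_approx);
    if (ok) {
      const double rss = yty - 2.0 * arma::dot(beta, gs) +
        arma::as_scalar(beta.t() * Gs * beta);
      r2[c] = 1.0 - rss / sst;
      arma::vec pred(nval, arma::fill::value(beta(0)));
      for (int i = 0; i < k; ++i) pred += beta(i + 1) * Xval.col(idx[i]);
      abserr = arma::abs(yval - pred);
      arma::vec se = arma::sort(abserr);           // ascending, keep smallest
      const arma::vec kept = se.head(nkeep);
      mae[c] = arma::mean(kept);
      sd_trim[c] = nkeep > 1 ? arma::stddev(kept) : 0.0;
    } else {
      r2[c] = NA_REAL;
      mae[c] = R_PosInf;
      sd_trim[c] = R_PosInf;
    }
    for (int i = 0; i < k; ++i) combos(i, c) = idx[i] + 1;

    // next lexicographic combination
    int i = k - 1;
    while (i >= 0 && idx[i] == p - k + i) --i;
    if (i < 0) break;
    ++idx[i];
    for (int j = i + 1; j < k; ++j) idx[j] = idx[j - 1] + 1;
  }

  return List::create(_["combos"] = combos, _["mae"] = mae,
                      _["sd_trim"] = sd_trim, _["r2"] = r2);
}
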