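// Hot numerical kernels: batched time-domain window features and the
// candidate-scoring loop of the LDA SFS wrapper. Both have exact R
// counterparts (extract_features(); the qda scorer in training.R) that the
// test suite cross-checks against.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// R type-7 quantile on an already sorted vector
static double quantile7(const arma::vec& sorted, double p) {
  const int n = sorted.n_elem;
  const double h = (n - 1) * p;
  const int lo = (int)std::floor(h);
  const double g = h - lo;
  return (lo + 1 < n) ? sorted[lo] + g * (sorted[lo + 1] - sorted[lo]) : sorted[lo];
}

// Time-domain feature block for a batch of equal-length signals (columns of
// X). Per signal, in order: std, min, max, median; the percentiles `probs`
// (type 7); sums of values below each low percentile then above each high
// one; the analogous square sums; level-crossing counts per percentile.
// [[Rcpp::export]]
arma::mat time_features_batch(const arma::mat& X, const arma::vec& probs) {
  const int W = X.n_rows, n = X.n_cols, P = probs.n_elem;
  std::vector<int> low, high;
  for (int p = 0; p < P; ++p) {
    if (probs[p] < 0.5) low.push_back(p);
    else if (probs[p] > 0.5) high.push_back(p);
  }
  const int ntail = low.size() + high.size();
  arma::mat out(n, 4 + P + 2 * ntail + P);
  arma::vec q(P);
  for (int j = 0; j < n; ++j) {
    const arma::vec x = X.col(j);
    const arma::vec sorted = arma::sort(x);
    for (int p = 0; p < P; ++p) q[p] = quantile7(sorted, probs[p]);
    int c = 0;
    out(j, c++) = arma::stddev(x);
    out(j, c++) = sorted[0];
    out(j, c++) = sorted[W - 1];
    out(j, c++) = quantile7(sorted, 0.5);
    for (int p = 0; p < P; ++p) out(j, c++) = q[p];
    for (int pass = 0; pass < 2; ++pass) {  // pass 0: sums, pass 1: square sums
      for (size_t t = 0; t < low.size(); ++t) {
        double s = 0;
        for (int i = 0; i < W; ++i)
          if (x[i] < q[low[t]]) s += pass ? x[i] * x[i] : x[i];
        out(j, c++) = s;
      }
      for (size_t t = 0; t < high.size(); ++t) {
        double s = 0;
        for (int i = 0; i < W; ++i)
          if (x[i] > q[high[t]]) s += pass ? x[i] * x[i] : x[i];
        out(j, c++) = s;
      }
    }
    for (int p = 0; p < P; ++p) {
      int prev = 0, cnt = 0;
      for (int i = 0; i < W; ++i) {
        const double d = x[i] - q[p];
        const int s = (d > 0) - (d < 0);
        if (s != 0) {
          if (prev != 0 && s != prev) ++cnt;
          prev = s;
        }
      }
      out(j, c++) = cnt;
    }
  }
  return out;
}

static double ba_from_preds(const arma::ivec& truth, const arma::ivec& pred, int K) {
  arma::vec den(K, arma::fill::zeros), num(K, arma::fill::zeros);
  for (arma::uword i = 0; i < truth.n_elem; ++i) {
    den[truth[i] - 1] += 1.0;
    if (truth[i] == pred[i]) num[truth[i] - 1] += 1.0;
  }
  double s = 0;
  int c = 0;
  for (int k = 0; k < K; ++k)
    if (den[k] > 0) { s += num[k] / den[k]; ++c; }
  return c ? s / c : 0.0;
}

// Balanced accuracy of an LDA classifier, rebuilt from cached training
// moments, for every candidate feature subset {selected + candidate}.
// SW: pooled within-class scatter over all features; M: class means for the
// classes present in the training fold (rows align with `pres` and
// `logprior`); Xtest/ytest: held-out fold (ytest 1-based class codes over K
// classes); denom: scatter -> covariance divisor. Indices are 1-based.
// [[Rcpp::export]]
arma::vec lda_score_candidates(const arma::mat& SW, const arma::mat& M,
                               const arma::vec& logprior, const arma::mat& Xtest,
                               const arma::ivec& ytest, const arma::ivec& pres,
                               int K, const arma::ivec& selected,
                               const arma::ivec& candidates, double denom) {
  const int nsel = selected.n_elem, nc = candidates.n_elem;
  arma::vec out(nc, arma::fill::zeros);
  arma::uvec idx(nsel + 1);
  for (int s = 0; s < nsel; ++s) idx[s] = selected[s] - 1;
  for (int ci = 0; ci < nc; ++ci) {
    idx[nsel] = candidates[ci] - 1;
    arma::mat Sig = SW.submat(idx, idx) / denom;
    Sig.diag() += 1e-8 * (arma::trace(Sig) / Sig.n_rows + 1e-12);
    arma::mat Si;
    if (!arma::inv_sympd(Si, Sig)) continue;  // degenerate subset scores 0
    const arma::mat Mf = M.cols(idx);         // k x q
    const arma::mat Wm = Si * Mf.t();         // q x k
    arma::rowvec b = -0.5 * arma::sum(Mf.t() % Wm, 0) + logprior.t();
    arma::mat S = Xtest.cols(idx) * Wm;
    S.each_row() += b;
    arma::ivec pred(S.n_rows);
    for (arma::uword i = 0; i < S.n_rows; ++i) {
      arma::uword jmax;
      S.row(i).max(jmax);
      pred[i] = pres[jmax];
    }
    out[ci] = ba_from_preds(ytest, pred, K);
  }
  return out;
}
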