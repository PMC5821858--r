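#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Rank-based equiprobable binning: bin sizes differ by at most one sample,
// so each marginal is (near-)uniform by construction. Ties broken by input
// order (stable sort) -> deterministic.
static std::vector<int> equiprob_bins(const double* x, int n, int n_bins) {
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [x](int a, int b) { return x[a] < x[b]; });
  std::vector<int> bin(n);
  for (int i = 0; i < n; ++i)
    bin[ord[i]] = (int)(((long long)i * n_bins) / n);
  return bin;
}

static double mi_from_bins(const std::vector<int>& bx,
                           const std::vector<int>& by,
                           int n, int n_bins) {
  std::vector<int> joint(n_bins * n_bins, 0);
  std::vector<int> mx(n_bins, 0), my(n_bins, 0);
  for (int i = 0; i < n; ++i) {
    ++joint[bx[i] * n_bins + by[i]];
    ++mx[bx[i]];
    ++my[by[i]];
  }
  const double ln2 = std::log(2.0);
  double mi = 0.0;
  for (int a = 0; a < n_bins; ++a) {
    if (mx[a] == 0) continue;
    for (int b = 0; b < n_bins; ++b) {
      int c = joint[a * n_bins + b];
      if (c == 0 || my[b] == 0) continue;
      double pij = (double)c / n;
      mi += pij * std::log(pij * n * (double)n /
                           ((double)mx[a] * (double)my[b])) / ln2;
    }
  }
  if (mi < 0) mi = 0; // guard against rounding
  return mi;
}

// [[Rcpp::export]]
double mi_bits_cpp(NumericVector x, NumericVector y, int n_bins) {
  int n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  if (n_bins < 2) stop("n_bins must be >= 2");
  std::vector<int> bx = equiprob_bins(REAL(x), n, n_bins);
  std::vector<int> by = equiprob_bins(REAL(y), n, n_bins);
  return mi_from_bins(bx, by, n, n_bins);
}

// sig: samples x channels. Returns symmetric channels x channels MI matrix
// (bits), zero diagonal. Channels are binned once, pairs reuse the bins.
// [[Rcpp::export]]
NumericMatrix pairwise_mi_cpp(NumericMatrix sig, int n_bins) {
  int n = sig.nrow(), nc = sig.ncol();
  if (n_bins < 2) stop("n_bins must be >= 2");
  std::vector<std::vector<int> > bins(nc);
  for (int c = 0; c < nc; ++c)
    bins[c] = equiprob_bins(&sig(0, c), n, n_bins);
  NumericMatrix out(nc, nc);
  for (int i = 0; i < nc; ++i) {
    for (int j = i + 1; j < nc; ++j) {
      double mi = mi_from_bins(bins[i], bins[j], n, n_bins);
      out(i, j) = mi;
      out(j, i) = mi;
    }
  }
  return out;
}
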