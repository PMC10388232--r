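#include <Rcpp.h>
using namespace Rcpp;

// Accumulated-cost matrix for unconstrained DTW with absolute-difference
// local cost. Boundary sentinels: F(0,0) = 0, first row/column = +Inf.
// [[Rcpp::export(name = ".dtw_fill")]]
NumericMatrix dtw_fill(NumericVector r, NumericVector t) {
  const int n = r.size(), m = t.size();
  NumericMatrix F(n + 1, m + 1);
  std::fill(F.begin(), F.end(), R_PosInf);
  F(0, 0) = 0.0;
  for (int k = 1; k <= n; ++k) {
    const double rk = r[k - 1];
    for (int l = 1; l <= m; ++l) {
      const double d = std::fabs(rk - t[l - 1]);
      double best = F(k - 1, l - 1);
      if (F(k - 1, l) < best) best = F(k - 1, l);
      if (F(k, l - 1) < best) best = F(k, l - 1);
      F(k, l) = d + best;
    }
  }
  return F;
}

// Distance only, O(m) memory (two-row recurrence); identical value to the
// full-matrix fill.
// [[Rcpp::export(name = ".dtw_distance_only")]]
double dtw_distance_only(NumericVector r, NumericVector t) {
  const int n = r.size(), m = t.size();
  std::vector<double> prev(m + 1, R_PosInf), cur(m + 1);
  prev[0] = 0.0;
  for (int k = 1; k <= n; ++k) {
    const double rk = r[k - 1];
    cur[0] = R_PosInf;
    for (int l = 1; l <= m; ++l) {
      const double d = std::fabs(rk - t[l - 1]);
      double best = prev[l - 1];
      if (prev[l] < best) best = prev[l];
      if (cur[l - 1] < best) best = cur[l - 1];
      cur[l] = d + best;
    }
    prev.swap(cur);
  }
  return prev[m];
}

// Backtrack the optimal warping path from (n, m) to (1, 1). Ties are broken
// deterministically: diagonal first, then the predecessor reducing k, then
// the one reducing l. Returns a 2-column matrix of 1-based (k, l) pairs in
// forward order.
// [[Rcpp::export(name = ".dtw_backtrack")]]
IntegerMatrix dtw_backtrack(NumericMatrix F) {
  const int n = F.nrow() - 1, m = F.ncol() - 1;
  std::vector<std::pair<int, int> > rev;
  int k = n, l = m;
  rev.push_back(std::make_pair(k, l));
  while (k > 1 || l > 1) {
    const double diag = F(k - 1, l - 1);
    const double up = F(k - 1, l);
    const double left = F(k, l - 1);
    double best = diag;
    if (up < best) best = up;
    if (left < best) best = left;
    if (diag == best) {
      --k; --l;
    } else if (up == best) {
      --k;
    } else {
      --l;
    }
    rev.push_back(std::make_pair(k, l));
  }
  const int len = rev.size();
  IntegerMatrix path(len, 2);
  for (int i = 0; i < len; ++i) {
    path(i, 0) = rev[len - 1 - i].first;
    path(i, 1) = rev[len - 1 - i].second;
  }
  return path;
}
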