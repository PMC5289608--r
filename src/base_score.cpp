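#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Running-sum (BASE-style) preliminary scores for a batch of 0/1 target
// membership vectors against every sample column of an expression matrix.
//
// For one sample: genes are sorted by descending expression, ties broken by
// ascending gene index (stable). Foreground F(k) accumulates the (optionally
// |e|-weighted) mass of target genes seen up to rank k, background B(k) does
// the same for non-targets; both end at 1. The score is D(k*) = F - B at the
// rank k* maximising |D|, smallest k on ties. If a class's total weight is
// zero (all relevant |e| == 0), equal increments 1/count are used for it.
//
// expr: genes x samples; memb: genes x m of 0/1 (column 1 is typically the
// observed set, the rest permutation nulls). Returns m x samples scores.
// [[Rcpp::export]]
NumericMatrix base_scores_cpp(const NumericMatrix& expr,
                              const IntegerMatrix& memb,
                              const bool abs_weight) {
  const int n = expr.nrow(), s = expr.ncol(), m = memb.ncol();
  if (memb.nrow() != n) stop("membership/expression row mismatch");
  NumericMatrix out(m, s);
  std::vector<int> ord(n);
  std::vector<double> w(n);

  for (int col = 0; col < s; ++col) {
    const double* e = &expr(0, col);
    std::iota(ord.begin(), ord.end(), 0);
    std::stable_sort(ord.begin(), ord.end(),
                     [e](int a, int b) { return e[a] > e[b]; });
    for (int j = 0; j < n; ++j) w[j] = abs_weight ? std::fabs(e[j]) : 1.0;

    for (int mc = 0; mc < m; ++mc) {
      const int* tg = &memb(0, mc);
      double tot_fg = 0.0, tot_bg = 0.0;
      int n_fg = 0, n_bg = 0;
      for (int j = 0; j < n; ++j) {
        if (tg[j]) { tot_fg += w[j]; ++n_fg; } else { tot_bg += w[j]; ++n_bg; }
      }
      if (n_fg == 0 || n_bg == 0)
        stop("membership column %d has an empty target or background class",
             mc + 1);
      const bool unif_fg = (tot_fg == 0.0), unif_bg = (tot_bg == 0.0);
      double F = 0.0, B = 0.0, best = 0.0, best_abs = -1.0;
      for (int k = 0; k < n; ++k) {
        const int j = ord[k];
        if (tg[j]) F += unif_fg ? 1.0 / n_fg : w[j] / tot_fg;
        else       B += unif_bg ? 1.0 / n_bg : w[j] / tot_bg;
        const double d = F - B, a = std::fabs(d);
        if (a > best_abs) { best_abs = a; best = d; }
      }
      out(mc, col) = best;
    }
  }
  return out;
}
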