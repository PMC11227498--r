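#include <Rcpp.h>
#include <functional>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exhaustive enumeration for the Freeman-Halton exact test: visits every
// non-negative integer table with the observed margins (recursive
// row-major fill with column-remainder pruning) and accumulates the
// multivariate hypergeometric probability of tables whose probability
// does not exceed that of the observed table (relative tie tolerance
// rel_tol).  Aborts once more than `budget` cell assignments have been
// tried, signalling the caller to fall back to Monte Carlo.
// [[Rcpp::export]]
List ffh_enumerate(IntegerMatrix tab, double budget, double rel_tol) {
  const int r = tab.nrow(), c = tab.ncol();
  std::vector<int> rowsum(r, 0), colrem(c, 0);
  int n = 0;
  for (int i = 0; i < r; ++i)
    for (int j = 0; j < c; ++j) {
      rowsum[i] += tab(i, j);
      colrem[j] += tab(i, j);
      n += tab(i, j);
    }
  std::vector<double> lf(n + 1);
  lf[0] = 0.0;
  for (int i = 1; i <= n; ++i) lf[i] = lf[i - 1] + std::log((double)i);
  double cons = -lf[n];
  for (int i = 0; i < r; ++i) cons += lf[rowsum[i]];
  for (int j = 0; j < c; ++j) cons += lf[colrem[j]];
  double logp_obs = cons;
  for (int i = 0; i < r; ++i)
    for (int j = 0; j < c; ++j) logp_obs -= lf[tab(i, j)];
  const double thresh = logp_obs + std::log1p(rel_tol);

  long double p_le = 0.0L, p_tot = 0.0L;
  double nodes = 0.0, ntab = 0.0;
  bool ok = true;

  std::function<void(int, int, int, double)> rec =
      [&](int i, int j, int rowrem, double acc) {
        if (!ok) return;
        if (i == r - 1) {
          // last row is forced by the column remainders
          double a = acc;
          for (int jj = 0; jj < c; ++jj) a -= lf[colrem[jj]];
          double logp = cons + a;
          ntab += 1.0;
          long double p = expl((long double)logp);
          p_tot += p;
          if (logp <= thresh) p_le += p;
          return;
        }
        if (j == c - 1) {
          if (rowrem > colrem[j]) return;
          colrem[j] -= rowrem;
          rec(i + 1, 0, rowsum[i + 1], acc - lf[rowrem]);
          colrem[j] += rowrem;
          return;
        }
        int rest = 0;
        for (int jj = j + 1; jj < c; ++jj) rest += colrem[jj];
        const int lo = std::max(0, rowrem - rest);
        const int hi = std::min(rowrem, colrem[j]);
        for (int v = lo; v <= hi; ++v) {
          nodes += 1.0;
          if (nodes > budget) { ok = false; return; }
          colrem[j] -= v;
          rec(i, j + 1, rowrem - v, acc - lf[v]);
          colrem[j] += v;
        }
      };
  rec(0, 0, rowsum[0], 0.0);
  return List::create(_["p"] = (double)p_le,
                      _["total"] = (double)p_tot,
                      _["ntables"] = ntab,
                      _["nodes"] = nodes,
                      _["completed"] = ok,
                      _["logp_obs"] = logp_obs);
}
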