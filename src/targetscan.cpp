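#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Allen-rule miRNA target scoring: banded global alignment of the miRNA
// (5'->3') against the reversed target window (antiparallel duplex), with
// penalties mismatch 1.0, G:U wobble 0.5, gap 2.0, all doubled at miRNA
// positions 2-13 counted from the 5' end. Base codes: A=0, C=1, G=2, U/T=3.

static inline double wt(int i) { return (i >= 2 && i <= 13) ? 2.0 : 1.0; }

static inline double sub_cost(int mb, int tb, int i) {
  const bool wc = (mb == 0 && tb == 3) || (mb == 3 && tb == 0) ||
                  (mb == 1 && tb == 2) || (mb == 2 && tb == 1);
  if (wc) return 0.0;
  const bool gu = (mb == 2 && tb == 3) || (mb == 3 && tb == 2);
  return (gu ? 0.5 : 1.0) * wt(i);
}

// alignment penalty of mirna vs one reversed window; band limits gaps
static double align_window(const IntegerVector& mirna, const int* target,
                           int s, int w, int band) {
  const int m = mirna.size();
  const double BIG = 1e9;
  std::vector<std::vector<double> > D(m + 1, std::vector<double>(w + 1, BIG));
  D[0][0] = 0.0;
  for (int i = 1; i <= m && i <= band; ++i)
    D[i][0] = D[i - 1][0] + 2.0 * wt(i);
  for (int j = 1; j <= w && j <= band; ++j)
    D[0][j] = D[0][j - 1] + 2.0 * wt(1);
  for (int i = 1; i <= m; ++i) {
    const int jlo = std::max(1, i - band), jhi = std::min(w, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      const int tb = target[s + w - j]; // reversed window, 0-based
      double best = D[i - 1][j - 1] + sub_cost(mirna[i - 1], tb, i);
      if (D[i - 1][j] < BIG) best = std::min(best, D[i - 1][j] + 2.0 * wt(i));
      if (D[i][j - 1] < BIG)
        best = std::min(best, D[i][j - 1] + 2.0 * wt(std::min(i + 1, m)));
      D[i][j] = best;
    }
  }
  return D[m][w];
}

// [[Rcpp::export(name = ".allen_scan_cpp")]]
NumericMatrix allen_scan_cpp(IntegerVector mirna, IntegerVector target,
                             double cutoff, int max_gap) {
  const int m = mirna.size();
  const int n = target.size();
  std::vector<double> rs, re, rv;
  std::vector<int> tvec(target.begin(), target.end());
  for (int s = 0; s + m - max_gap <= n; ++s) {
    double best = 1e9;
    int bestw = -1;
    for (int w = m - max_gap; w <= m + max_gap; ++w) {
      if (w < 1 || s + w > n) continue;
      const double sc = align_window(mirna, tvec.data(), s, w, max_gap);
      if (sc < best) { best = sc; bestw = w; }
    }
    if (bestw > 0 && best <= cutoff) {
      rs.push_back(s + 1);        // 1-based start
      re.push_back(s + bestw);    // inclusive end
      rv.push_back(best);
    }
  }
  NumericMatrix out(rs.size(), 3);
  for (int k = 0; k < (int)rs.size(); ++k) {
    out(k, 0) = rs[k]; out(k, 1) = re[k]; out(k, 2) = rv[k];
  }
  colnames(out) = CharacterVector::create("start", "end", "score");
  return out;
}
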