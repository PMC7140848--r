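#include <Rcpp.h>
#include <climits>
#include <vector>
using namespace Rcpp;

// Minimum-free-energy secondary structure by a Zuker-style recursion over a
// simplified nearest-neighbor model (stacks + length-indexed loop penalties +
// affine multiloops, no dangles). Energies are handled as integers in hundredths
// of a kcal/mol, scaled so that ties in energy are broken in favor of the
// structure with more base pairs:
//   cost = energy_centikcal * 1000 - n_pairs
// Any two structures differing in energy differ in cost by >= 1000 while the
// pair-count correction is bounded by the sequence length (<= 400), so energy
// strictly dominates and the pair count only resolves exact energy ties.

static const int INF = INT_MAX / 4;

// base codes: A=0, C=1, G=2, U=3
// pair codes: AU=0, UA=1, GC=2, CG=3, GU=4, UG=5, none=-1
static inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 1 && b == 2) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

struct Params {
  int stack[6][6];            // centi-kcal
  std::vector<int> hairpin;   // 1-based by loop size, centi-kcal
  std::vector<int> bulge;
  std::vector<int> internal_; // by total unpaired
  int ml_init, ml_branch, ml_unpaired; // centi-kcal
  int pair_bonus;             // centi-kcal, applied once per pair
  int min_hairpin;
  int max_loop;
};

static inline int loop_tab(const std::vector<int>& tab, int n) {
  if (n <= 0 || n >= (int)tab.size()) return INF;
  return tab[n];
}

// cost of the loop closed by (i,j) with inner pair (p,q); excludes V(p,q) and
// the per-pair cost of either pair
static inline int interior_cost(const Params& P, int pt_ij, int pt_pq,
                                int n1, int n2) {
  if (n1 == 0 && n2 == 0) return P.stack[pt_ij][pt_pq] * 1000;
  int e;
  if (n1 == 0 || n2 == 0) e = loop_tab(P.bulge, n1 + n2);
  else e = loop_tab(P.internal_, n1 + n2);
  if (e >= INF) return INF;
  return e * 1000;
}

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(IntegerVector seq, NumericMatrix stack_kcal,
                  NumericVector hairpin_kcal, NumericVector bulge_kcal,
                  NumericVector internal_kcal, double ml_init, double ml_branch,
                  double ml_unpaired, double pair_bonus, int min_hairpin,
                  int max_loop) {
  const int n = seq.size();
  Params P;
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 6; ++b)
      P.stack[a][b] = (int)lround(stack_kcal(a, b) * 100.0);
  P.hairpin.assign(hairpin_kcal.size() + 1, INF);
  for (int k = 0; k < hairpin_kcal.size(); ++k)
    P.hairpin[k + 1] = R_finite(hairpin_kcal[k]) ?
      (int)lround(hairpin_kcal[k] * 100.0) : INF;
  P.bulge.assign(bulge_kcal.size() + 1, INF);
  for (int k = 0; k < bulge_kcal.size(); ++k)
    P.bulge[k + 1] = R_finite(bulge_kcal[k]) ?
      (int)lround(bulge_kcal[k] * 100.0) : INF;
  P.internal_.assign(internal_kcal.size() + 1, INF);
  for (int k = 0; k < internal_kcal.size(); ++k)
    P.internal_[k + 1] = R_finite(internal_kcal[k]) ?
      (int)lround(internal_kcal[k] * 100.0) : INF;
  P.ml_init = (int)lround(ml_init * 100.0);
  P.ml_branch = (int)lround(ml_branch * 100.0);
  P.ml_unpaired = (int)lround(ml_unpaired * 100.0);
  P.pair_bonus = (int)lround(pair_bonus * 100.0);
  P.min_hairpin = min_hairpin;
  P.max_loop = max_loop;

  if (n < 2) {
    return List::create(_["pairs"] = IntegerMatrix(0, 2), _["mfe"] = 0.0);
  }

  std::vector<std::vector<int> > V(n, std::vector<int>(n, INF));
  std::vector<std::vector<int> > WM(n, std::vector<int>(n, INF));
  const int pair_cost = P.pair_bonus * 1000 - 1; // per-pair contribution

  for (int span = P.min_hairpin + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      const int j = i + span;
      const int pt = pair_type(seq[i], seq[j]);
      if (pt >= 0) {
        int best = INF;
        // hairpin
        int hp = loop_tab(P.hairpin, j - i - 1);
        if (hp < INF) best = std::min(best, hp * 1000);
        // stack / bulge / internal
        for (int p = i + 1; p <= std::min(i + P.max_loop + 1, j - 2); ++p) {
          const int n1 = p - i - 1;
          const int qmin = std::max(p + P.min_hairpin + 1,
                                    j - 1 - (P.max_loop - n1));
          for (int q = j - 1; q >= qmin; --q) {
            if (V[p][q] >= INF) continue;
            const int ptin = pair_type(seq[p], seq[q]);
            const int lc = interior_cost(P, pt, ptin, n1, j - q - 1);
            if (lc >= INF) continue;
            best = std::min(best, lc + V[p][q]);
          }
        }
        // multiloop: closing pair + >= 2 inner branches
        if (j - i - 1 >= 2 * (P.min_hairpin + 2)) {
          const int mlb = (P.ml_init + P.ml_branch) * 1000;
          for (int k = i + 1; k < j - 1; ++k) {
            if (WM[i + 1][k] >= INF || WM[k + 1][j - 1] >= INF) continue;
            best = std::min(best, mlb + WM[i + 1][k] + WM[k + 1][j - 1]);
          }
        }
        if (best < INF) V[i][j] = best + pair_cost;
      }
      // WM: part of a multiloop containing >= 1 branch
      int wm = INF;
      if (V[i][j] < INF) wm = std::min(wm, V[i][j] + P.ml_branch * 1000);
      if (i + 1 <= j && WM[i + 1][j] < INF)
        wm = std::min(wm, WM[i + 1][j] + P.ml_unpaired * 1000);
      if (j - 1 >= i && WM[i][j - 1] < INF)
        wm = std::min(wm, WM[i][j - 1] + P.ml_unpaired * 1000);
      for (int k = i; k < j; ++k) {
        if (WM[i][k] >= INF || WM[k + 1][j] >= INF) continue;
        wm = std::min(wm, WM[i][k] + WM[k + 1][j]);
      }
      WM[i][j] = wm;
    }
  }

  // external loop, unpaired bases free
  std::vector<int> W(n + 1, 0); // W[j+1] = best cost over prefix [0..j]
  for (int j = 0; j < n; ++j) {
    int best = W[j]; // j unpaired
    for (int i = 0; i <= j - P.min_hairpin - 1; ++i) {
      if (V[i][j] >= INF) continue;
      best = std::min(best, W[i] + V[i][j]);
    }
    W[j + 1] = best;
  }

  // traceback
  std::vector<std::pair<int,int> > pairs;
  std::vector<std::pair<std::pair<int,int>, int> > stack_tb; // ((i,j), kind) kind 0=V,1=WM
  {
    int j = n - 1;
    while (j >= 0) {
      if (W[j + 1] == W[j]) { --j; continue; }
      bool found = false;
      for (int i = 0; i <= j - P.min_hairpin - 1 && !found; ++i) {
        if (V[i][j] < INF && W[i] + V[i][j] == W[j + 1]) {
          stack_tb.push_back(std::make_pair(std::make_pair(i, j), 0));
          j = i - 1;
          found = true;
        }
      }
      if (!found) stop("traceback failure in external loop");
    }
  }
  while (!stack_tb.empty()) {
    const int i = stack_tb.back().first.first;
    const int j = stack_tb.back().first.second;
    const int kind = stack_tb.back().second;
    stack_tb.pop_back();
    if (kind == 0) {
      pairs.push_back(std::make_pair(i, j));
      const int target = V[i][j] - pair_cost;
      const int pt = pair_type(seq[i], seq[j]);
      const int hp = loop_tab(P.hairpin, j - i - 1);
      if (hp < INF && target == hp * 1000) continue;
      bool found = false;
      for (int p = i + 1; p <= std::min(i + P.max_loop + 1, j - 2) && !found; ++p) {
        const int n1 = p - i - 1;
        const int qmin = std::max(p + P.min_hairpin + 1,
                                  j - 1 - (P.max_loop - n1));
        for (int q = j - 1; q >= qmin && !found; --q) {
          if (V[p][q] >= INF) continue;
          const int ptin = pair_type(seq[p], seq[q]);
          const int lc = interior_cost(P, pt, ptin, n1, j - q - 1);
          if (lc < INF && target == lc + V[p][q]) {
            stack_tb.push_back(std::make_pair(std::make_pair(p, q), 0));
            found = true;
          }
        }
      }
      if (!found && j - i - 1 >= 2 * (P.min_hairpin + 2)) {
        const int mlb = (P.ml_init + P.ml_branch) * 1000;
        for (int k = i + 1; k < j - 1 && !found; ++k) {
          if (WM[i + 1][k] >= INF || WM[k + 1][j - 1] >= INF) continue;
          if (target == mlb + WM[i + 1][k] + WM[k + 1][j - 1]) {
            stack_tb.push_back(std::make_pair(std::make_pair(i + 1, k), 1));
            stack_tb.push_back(std::make_pair(std::make_pair(k + 1, j - 1), 1));
            found = true;
          }
        }
      }
      if (!found) stop("traceback failure in V");
    } else {
      const int target = WM[i][j];
      if (V[i][j] < INF && target == V[i][j] + P.ml_branch * 1000) {
        stack_tb.push_back(std::make_pair(std::make_pair(i, j), 0));
        continue;
      }
      if (i + 1 <= j && WM[i + 1][j] < INF &&
          target == WM[i + 1][j] + P.ml_unpaired * 1000) {
        stack_tb.push_back(std::make_pair(std::make_pair(i + 1, j), 1));
        continue;
      }
      if (j - 1 >= i && WM[i][j - 1] < INF &&
          target == WM[i][j - 1] + P.ml_unpaired * 1000) {
        stack_tb.push_back(std::make_pair(std::make_pair(i, j - 1), 1));
        continue;
      }
      bool found = false;
      for (int k = i; k < j && !found; ++k) {
        if (WM[i][k] >= INF || WM[k + 1][j] >= INF) continue;
        if (target == WM[i][k] + WM[k + 1][j]) {
          stack_tb.push_back(std::make_pair(std::make_pair(i, k), 1));
          stack_tb.push_back(std::make_pair(std::make_pair(k + 1, j), 1));
          found = true;
        }
      }
      if (!found) stop("traceback failure in WM");
    }
  }

  const int npairs = (int)pairs.size();
  const int cost = W[n];
  const long e100 = ((long)cost + npairs) / 1000L;
  IntegerMatrix pm(npairs, 2);
  for (int k = 0; k < npairs; ++k) {
    pm(k, 0) = pairs[k].first + 1;  // 1-based for R
    pm(k, 1) = pairs[k].second + 1;
  }
  return List::create(_["pairs"] = pm, _["mfe"] = (double)e100 / 100.0);
}
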