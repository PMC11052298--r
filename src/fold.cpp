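// Minimum-folding-energy dynamic program for short RNA windows.
//
// Zuker-style recursion over a compact nearest-neighbour parameter set:
// stacking energies for Watson-Crick + GU stacks, length penalties for
// hairpin / bulge / internal loops (Jacobson-Stockmayer extrapolation),
// and an affine multiloop cost. Minimum hairpin loop 3, interior loops
// capped at 30 unpaired nucleotides, no dangles or terminal-pair terms.
// The same parameter set is exposed to R via fold_params() so that an
// exhaustive enumeration oracle can score structures identically.

#include <Rcpp.h>
#include <cmath>
#include <string>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double INF = 1e9;
static const double RT37 = 0.61633; // kcal/mol at 37 C
static const double JS_COEF = 1.75; // Jacobson-Stockmayer prefactor

// pair types: 0 = none, 1 CG, 2 GC, 3 GU, 4 UG, 5 AU, 6 UA
static int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'U': case 'u': case 'T': case 't': return 3;
  default: return -1; // ambiguity codes: unpairable
  }
}

static int pair_type(int a, int b) {
  if (a < 0 || b < 0) return 0;
  if (a == 1 && b == 2) return 1; // CG
  if (a == 2 && b == 1) return 2; // GC
  if (a == 2 && b == 3) return 3; // GU
  if (a == 3 && b == 2) return 4; // UG
  if (a == 0 && b == 3) return 5; // AU
  if (a == 3 && b == 0) return 6; // UA
  return 0;
}

// stack[outer][inner], outer pair (i,j), inner pair (i+1, j-1)
static const double STACK[7][7] = {
  {0, 0, 0, 0, 0, 0, 0},
  {0, -3.3, -2.4, -2.1, -1.4, -2.1, -2.1}, // CG
  {0, -3.4, -3.3, -2.5, -1.5, -2.2, -2.4}, // GC
  {0, -2.5, -2.1, -1.3, -0.5, -1.4, -1.3}, // GU
  {0, -2.4, -2.2, -0.5, -0.3, -1.0, -0.6}, // UG
  {0, -2.4, -2.1, -1.3, -1.0, -0.9, -1.1}, // AU
  {0, -2.4, -2.1, -1.3, -1.0, -1.3, -0.9}  // UA
};

static const double HAIRPIN[10] = {INF, INF, INF, 5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4};
static const double BULGE[7]    = {INF, 3.8, 2.8, 3.2, 3.6, 4.0, 4.4};
static const double IN_LOOP[11] = {INF, INF, 1.5, 1.6, 1.7, 2.0, 2.0, 2.2, 2.3, 2.4, 2.5};

static const double ML_CLOSE = 3.4;  // multiloop closing penalty
static const double ML_BRANCH = 0.4; // per branch
static const double ML_UNPAIRED = 0.1; // per unpaired base in the loop
static const int MIN_HAIRPIN = 3;
static const int MAX_LOOP = 30;

static double hairpin_energy(int l) {
  if (l < MIN_HAIRPIN) return INF;
  if (l <= 9) return HAIRPIN[l];
  return HAIRPIN[9] + JS_COEF * RT37 * std::log((double)l / 9.0);
}

static double bulge_energy(int l) {
  if (l < 1) return INF;
  if (l <= 6) return BULGE[l];
  return BULGE[6] + JS_COEF * RT37 * std::log((double)l / 6.0);
}

static double internal_energy(int l) {
  if (l < 2) return INF;
  if (l <= 10) return IN_LOOP[l];
  return IN_LOOP[10] + JS_COEF * RT37 * std::log((double)l / 10.0);
}

static double fold_one(const std::string& seq) {
  const int n = (int)seq.size();
  if (n < MIN_HAIRPIN + 2) return 0.0;
  std::vector<int> b(n);
  for (int i = 0; i < n; ++i) b[i] = base_code(seq[i]);

  // 0-based indices; V[i][j] etc with j > i
  std::vector<std::vector<double> > V(n, std::vector<double>(n, INF));
  std::vector<std::vector<double> > M1(n, std::vector<double>(n, INF));
  std::vector<std::vector<double> > WM(n, std::vector<double>(n, INF));

  for (int d = MIN_HAIRPIN + 1; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      int ptij = pair_type(b[i], b[j]);
      if (ptij != 0) {
        double best = hairpin_energy(j - i - 1);
        // stack / bulge / internal via interior pair (p, q)
        for (int p = i + 1; p < j - 1; ++p) {
          int l1 = p - i - 1;
          if (l1 > MAX_LOOP) break;
          for (int q = j - 1; q > p; --q) {
            int l2 = j - q - 1;
            if (l1 + l2 > MAX_LOOP) break;
            if (V[p][q] >= INF) continue;
            int ptpq = pair_type(b[p], b[q]);
            if (ptpq == 0) continue;
            double loop;
            if (l1 == 0 && l2 == 0) loop = STACK[ptij][ptpq];
            else if (l1 == 0 || l2 == 0) loop = bulge_energy(l1 + l2);
            else loop = internal_energy(l1 + l2);
            double e = loop + V[p][q];
            if (e < best) best = e;
          }
        }
        // multiloop: >= 2 branches inside
        for (int k = i + 2; k <= j - 2; ++k) {
          if (WM[i + 1][k - 1] >= INF || M1[k][j - 1] >= INF) continue;
          double e = ML_CLOSE + WM[i + 1][k - 1] + M1[k][j - 1];
          if (e < best) best = e;
        }
        V[i][j] = best;
      }
      // M1: exactly one branch starting at i, trailing unpaired
      double m1 = INF;
      if (j - 1 >= i && M1[i][j - 1] < INF) m1 = M1[i][j - 1] + ML_UNPAIRED;
      if (V[i][j] < INF) m1 = std::min(m1, V[i][j] + ML_BRANCH);
      M1[i][j] = m1;
      // WM: >= 1 branch anywhere in [i, j]
      double wm = INF;
      if (i + 1 <= j && WM[i + 1][j] < INF) wm = WM[i + 1][j] + ML_UNPAIRED;
      wm = std::min(wm, M1[i][j]);
      for (int k = i + 1; k <= j; ++k) {
        if (WM[i][k - 1] < INF && M1[k][j] < INF)
          wm = std::min(wm, WM[i][k - 1] + M1[k][j]);
      }
      WM[i][j] = wm;
    }
  }

  std::vector<double> W(n + 1, 0.0);
  for (int j = 1; j <= n; ++j) {
    W[j] = W[j - 1];
    for (int k = 1; k <= j; ++k) {
      if (V[k - 1][j - 1] < INF)
        W[j] = std::min(W[j], W[k - 1] + V[k - 1][j - 1]);
    }
  }
  return std::min(0.0, W[n]);
}

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
NumericVector fold_mfe_cpp(CharacterVector seqs) {
  const int n = seqs.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = fold_one(std::string(seqs[i]));
  }
  return out;
}

// [[Rcpp::export(name = ".fold_params_cpp")]]
List fold_params_cpp() {
  NumericMatrix st(6, 6);
  CharacterVector pn = CharacterVector::create("CG", "GC", "GU", "UG", "AU", "UA");
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) st(i, j) = STACK[i + 1][j + 1];
  st.attr("dimnames") = List::create(pn, pn);
  NumericVector hp(7), bg(6), in_(9);
  for (int l = 3; l <= 9; ++l) hp[l - 3] = HAIRPIN[l];
  for (int l = 1; l <= 6; ++l) bg[l - 1] = BULGE[l];
  for (int l = 2; l <= 10; ++l) in_[l - 2] = IN_LOOP[l];
  hp.attr("names") = CharacterVector::create("3", "4", "5", "6", "7", "8", "9");
  bg.attr("names") = CharacterVector::create("1", "2", "3", "4", "5", "6");
  in_.attr("names") = CharacterVector::create("2", "3", "4", "5", "6", "7", "8", "9", "10");
  return List::create(
    _["stack"] = st, _["hairpin"] = hp, _["bulge"] = bg, _["internal"] = in_,
    _["ml_close"] = ML_CLOSE, _["ml_branch"] = ML_BRANCH,
    _["ml_unpaired"] = ML_UNPAIRED, _["min_hairpin"] = MIN_HAIRPIN,
    _["max_loop"] = MAX_LOOP, _["rt"] = RT37, _["js_coef"] = JS_COEF
  );
}
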