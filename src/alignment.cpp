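#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Affine-gap dynamic programming (Gotoh) over integer-encoded sequences.
// mode: 0 = local (Smith-Waterman), 1 = global (Needleman-Wunsch),
//       2 = overlap (global with free end gaps).
// A gap of length L costs gap_open + gap_extend * L.

static const double NEG = -1e18;

struct AlnStats {
  double score;
  int matches, cols, q_res, s_res;
  int q_start, q_end, s_start, s_end; // 1-based, inclusive; 0 if empty
};

// traceback codes for H: 0 stop, 1 diag, 2 enter E (gap in query rows? see below), 3 enter F
// E[i][j]: best ending with gap in A (consumes b[j]) -> move left
// F[i][j]: best ending with gap in B (consumes a[i]) -> move up
static AlnStats align_core(const int* a, int n, const int* b, int m,
                           const NumericMatrix& sub, double go, double ge, int mode,
                           std::vector<int>* pa, std::vector<int>* pb) {
  std::vector<double> Hprev(m + 1), Hcur(m + 1), Eprev(m + 1), Ecur(m + 1), Fcol(m + 1);
  // full traceback matrices (bytes)
  size_t sz = (size_t)(n + 1) * (m + 1);
  std::vector<unsigned char> tbH(sz, 0), tbE(sz, 0), tbF(sz, 0);
  std::vector<double> H((n + 1) * 0); // placeholder; we keep rolling rows but full tb
  // we need F per column across rows: keep vectors F and H of previous row
  std::vector<double> Hrow(m + 1), Erow(m + 1), Frow(m + 1), HrowPrev(m + 1), FrowPrev(m + 1);

  auto IDX = [m](int i, int j) { return (size_t)i * (m + 1) + j; };

  // init row 0
  HrowPrev[0] = 0.0;
  for (int j = 1; j <= m; ++j) {
    if (mode == 1) { // global: leading gap in A
      HrowPrev[j] = -(go + ge * j);
      tbH[IDX(0, j)] = 2;
      tbE[IDX(0, j)] = (unsigned char)(j > 1); // extend beyond first
    } else {
      HrowPrev[j] = 0.0;
    }
    FrowPrev[j] = NEG;
  }
  FrowPrev[0] = NEG;

  double best = (mode == 0) ? 0.0 : NEG;
  int bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    if (mode == 1) {
      Hrow[0] = -(go + ge * i);
      tbH[IDX(i, 0)] = 3;
      tbF[IDX(i, 0)] = (unsigned char)(i > 1);
    } else {
      Hrow[0] = 0.0;
    }
    Erow[0] = NEG;
    double Eleft = NEG; // E[i][j] computed left-to-right
    for (int j = 1; j <= m; ++j) {
      // E: gap in A, from left
      double e_open = Hrow[j - 1] - go - ge;
      double e_ext = Eleft - ge;
      double E;
      if (e_ext > e_open) { E = e_ext; tbE[IDX(i, j)] = 1; } else { E = e_open; tbE[IDX(i, j)] = 0; }
      // F: gap in B, from up
      double f_open = HrowPrev[j] - go - ge;
      double f_ext = FrowPrev[j] - ge;
      double F;
      if (f_ext > f_open) { F = f_ext; tbF[IDX(i, j)] = 1; } else { F = f_open; tbF[IDX(i, j)] = 0; }
      double diag = HrowPrev[j - 1] + sub(a[i - 1], b[j - 1]);
      double h = diag; unsigned char tb = 1;
      if (E > h) { h = E; tb = 2; }
      if (F > h) { h = F; tb = 3; }
      if (mode == 0 && h <= 0.0) { h = 0.0; tb = 0; }
      Hrow[j] = h; tbH[IDX(i, j)] = tb;
      Erow[j] = E; Frow[j] = F;
      Eleft = E;
      if (mode == 0) {
        if (h > best) { best = h; bi = i; bj = j; }
      } else if (mode == 2) {
        if ((i == n || j == m) && h > best) { best = h; bi = i; bj = j; }
      }
    }
    std::swap(HrowPrev, Hrow);
    std::swap(FrowPrev, Frow);
  }
  if (mode == 1) { best = HrowPrev[m]; bi = n; bj = m; }
  if (mode == 2 && m == 0) { best = 0; bi = n; bj = 0; }

  AlnStats st; st.score = best; st.matches = 0; st.cols = 0;
  st.q_res = 0; st.s_res = 0; st.q_start = 0; st.q_end = 0; st.s_start = 0; st.s_end = 0;

  if (mode == 0 && best <= 0.0) return st; // empty local alignment

  // traceback
  int i = bi, j = bj, state = 0; // 0 = H
  st.q_end = bi; st.s_end = bj;
  std::vector<std::pair<int,int> > steps; // (ai, bj) 1-based, 0 = gap
  while (true) {
    if (state == 0) {
      if (mode == 0 && (i == 0 || j == 0)) break;
      if (mode != 0 && i == 0 && j == 0) break;
      if (mode == 2 && (i == 0 || j == 0)) break; // free end gaps not emitted
      unsigned char tb = tbH[IDX(i, j)];
      if (tb == 0) break;
      if (tb == 1) { steps.push_back(std::make_pair(i, j)); --i; --j; }
      else if (tb == 2) state = 2;
      else state = 3;
    } else if (state == 2) { // in E: gap in A, consume b[j]
      unsigned char tb = tbE[IDX(i, j)];
      steps.push_back(std::make_pair(0, j));
      --j;
      if (!tb) state = 0;
    } else { // in F: gap in B, consume a[i]
      unsigned char tb = tbF[IDX(i, j)];
      steps.push_back(std::make_pair(i, 0));
      --i;
      if (!tb) state = 0;
    }
  }
  st.q_start = i + 1; st.s_start = j + 1;
  // steps are reversed
  for (int k = (int)steps.size() - 1; k >= 0; --k) {
    int ai = steps[k].first, bj2 = steps[k].second;
    ++st.cols;
    if (ai > 0) ++st.q_res;
    if (bj2 > 0) ++st.s_res;
    if (ai > 0 && bj2 > 0 && a[ai - 1] == b[bj2 - 1]) ++st.matches;
    if (pa) {
      pa->push_back(ai > 0 ? ai : NA_INTEGER);
      pb->push_back(bj2 > 0 ? bj2 : NA_INTEGER);
    }
  }
  if (st.cols == 0) { st.q_start = 0; st.s_start = 0; st.q_end = 0; st.s_end = 0; }
  return st;
}

// [[Rcpp::export]]
NumericMatrix cpp_align_stats(List aseqs, List bseqs, NumericMatrix sub,
                              double gap_open, double gap_extend, int mode) {
  int np = aseqs.size();
  if (bseqs.size() != np) stop("aseqs and bseqs must have equal length");
  NumericMatrix out(np, 9);
  colnames(out) = CharacterVector::create("score", "matches", "cols", "q_res", "s_res",
                                          "q_start", "q_end", "s_start", "s_end");
  for (int p = 0; p < np; ++p) {
    IntegerVector a = aseqs[p], b = bseqs[p];
    AlnStats st = align_core(a.begin(), a.size(), b.begin(), b.size(),
                             sub, gap_open, gap_extend, mode, NULL, NULL);
    out(p, 0) = st.score; out(p, 1) = st.matches; out(p, 2) = st.cols;
    out(p, 3) = st.q_res; out(p, 4) = st.s_res;
    out(p, 5) = st.q_start; out(p, 6) = st.q_end; out(p, 7) = st.s_start; out(p, 8) = st.s_end;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_align_path(IntegerVector a, IntegerVector b, NumericMatrix sub,
                    double gap_open, double gap_extend, int mode) {
  std::vector<int> pa, pb;
  AlnStats st = align_core(a.begin(), a.size(), b.begin(), b.size(),
                           sub, gap_open, gap_extend, mode, &pa, &pb);
  return List::create(
    _["score"] = st.score, _["matches"] = st.matches, _["cols"] = st.cols,
    _["q_res"] = st.q_res, _["s_res"] = st.s_res,
    _["q_start"] = st.q_start, _["q_end"] = st.q_end,
    _["s_start"] = st.s_start, _["s_end"] = st.s_end,
    _["path_a"] = wrap(pa), _["path_b"] = wrap(pb));
}

// Global affine-gap path over a precomputed column-vs-column score matrix S
// (profile-profile alignment). Returns steps: 1 diag, 2 gap in B (A column
// advances), 3 gap in A.
// [[Rcpp::export]]
IntegerVector cpp_profile_path(NumericMatrix S, double gap_open, double gap_extend) {
  int n = S.nrow(), m = S.ncol();
  size_t sz = (size_t)(n + 1) * (m + 1);
  std::vector<unsigned char> tbH(sz, 0), tbE(sz, 0), tbF(sz, 0);
  std::vector<double> HrowPrev(m + 1), Hrow(m + 1), FrowPrev(m + 1), Frow(m + 1);
  auto IDX = [m](int i, int j) { return (size_t)i * (m + 1) + j; };
  HrowPrev[0] = 0; FrowPrev[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    HrowPrev[j] = -(gap_open + gap_extend * j);
    tbH[IDX(0, j)] = 2; tbE[IDX(0, j)] = (unsigned char)(j > 1);
    FrowPrev[j] = NEG;
  }
  for (int i = 1; i <= n; ++i) {
    Hrow[0] = -(gap_open + gap_extend * i);
    tbH[IDX(i, 0)] = 3; tbF[IDX(i, 0)] = (unsigned char)(i > 1);
    double Eleft = NEG;
    for (int j = 1; j <= m; ++j) {
      double e_open = Hrow[j - 1] - gap_open - gap_extend;
      double e_ext = Eleft - gap_extend;
      double E; if (e_ext > e_open) { E = e_ext; tbE[IDX(i, j)] = 1; } else { E = e_open; tbE[IDX(i, j)] = 0; }
      double f_open = HrowPrev[j] - gap_open - gap_extend;
      double f_ext = FrowPrev[j] - gap_extend;
      double F; if (f_ext > f_open) { F = f_ext; tbF[IDX(i, j)] = 1; } else { F = f_open; tbF[IDX(i, j)] = 0; }
      double h = HrowPrev[j - 1] + S(i - 1, j - 1); unsigned char tb = 1;
      if (E > h) { h = E; tb = 2; }
      if (F > h) { h = F; tb = 3; }
      Hrow[j] = h; tbH[IDX(i, j)] = tb; Frow[j] = F; Eleft = E;
    }
    std::swap(HrowPrev, Hrow); std::swap(FrowPrev, Frow);
  }
  std::vector<int> steps;
  int i = n, j = m, state = 0;
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char tb = tbH[IDX(i, j)];
      if (tb == 1) { steps.push_back(1); --i; --j; }
      else if (tb == 2) state = 2;
      else state = 3;
    } else if (state == 2) {
      unsigned char tb = tbE[IDX(i, j)];
      steps.push_back(3); --j;
      if (!tb) state = 0;
    } else {
      unsigned char tb = tbF[IDX(i, j)];
      steps.push_back(2); --i;
      if (!tb) state = 0;
    }
  }
  std::reverse(steps.begin(), steps.end());
  return wrap(steps);
}
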