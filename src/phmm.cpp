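#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Plan-7-like profile HMM scoring: match/insert/delete states over m match
// columns, with flanking inserts (I0 before M1, Im after Mm) that emit from
// the background. Sequence must pass through all match/delete columns
// (glocal: global in the model, flanks absorbed by I0/Im).
//
// Parameters arrive as log-space matrices:
//   em   : m x K  log emission odds (log P_match(a) - log P_bg(a))
//   trans: list of log transition prob matrices, each m+1 rows:
//     row j (0-based) = transitions taken between column j and j+1
//     tmm, tmi, tmd, tim, tii, tdm, tdd
// Insert emissions equal the background, so inserts contribute only their
// transition costs to the log-odds.

static inline double lse(double a, double b) {
  if (a == -INFINITY) return b;
  if (b == -INFINITY) return a;
  double m = a > b ? a : b;
  return m + log(exp(a - m) + exp(b - m));
}
static inline double lse3(double a, double b, double c) {
  return lse(lse(a, b), c);
}

// core DP; forward = true: log-sum-exp, false: Viterbi (max)
static double phmm_dp(const NumericMatrix& em,
                      const IntegerVector& seq,   // 0-based residue index, -1 = unknown
                      const NumericMatrix& tmm, const NumericMatrix& tmi,
                      const NumericMatrix& tmd, const NumericMatrix& tim,
                      const NumericMatrix& tii, const NumericMatrix& tdm,
                      const NumericMatrix& tdd,
                      bool forward) {
  const int m = em.nrow();
  const int L = seq.size();
  const double NEG = -INFINITY;
  // dp arrays indexed by model column 0..m (0 = begin), per sequence prefix
  std::vector<double> M_prev(m + 1, NEG), I_prev(m + 1, NEG), D_prev(m + 1, NEG);
  std::vector<double> M_cur(m + 1, NEG), I_cur(m + 1, NEG), D_cur(m + 1, NEG);

  // i = 0 (no residues consumed): begin state at column 0
  M_prev[0] = 0.0;  // "M0" == begin
  for (int j = 1; j <= m; ++j) {
    // delete path from begin: B->D1 uses tmd[0], D->D uses tdd[j-1]
    double from_m = M_prev[j - 1] + tmd(j - 1, 0);
    double from_d = D_prev[j - 1] + tdd(j - 1, 0);
    D_prev[j] = forward ? lse(from_m, from_d) : std::max(from_m, from_d);
  }

  auto comb = [forward](double a, double b, double c) {
    return forward ? lse3(a, b, c) : std::max(std::max(a, b), c);
  };

  for (int i = 1; i <= L; ++i) {
    int a = seq[i - 1];
    std::fill(M_cur.begin(), M_cur.end(), NEG);
    std::fill(I_cur.begin(), I_cur.end(), NEG);
    std::fill(D_cur.begin(), D_cur.end(), NEG);
    // insert at column 0 (N-terminal flank)
    {
      double from_m = M_prev[0] + tmi(0, 0);
      double from_i = I_prev[0] + tii(0, 0);
      I_cur[0] = forward ? lse(from_m, from_i) : std::max(from_m, from_i);
      // emission log-odds 0 (background)
    }
    for (int j = 1; j <= m; ++j) {
      double e = (a >= 0) ? em(j - 1, a) : 0.0;  // unknown residue: odds 1
      double mm = M_prev[j - 1] + tmm(j - 1, 0);
      double im = I_prev[j - 1] + tim(j - 1, 0);
      double dm = D_prev[j - 1] + tdm(j - 1, 0);
      M_cur[j] = comb(mm, im, dm) + e;
      double mi = M_prev[j] + tmi(j, 0);
      double ii = I_prev[j] + tii(j, 0);
      I_cur[j] = (forward ? lse(mi, ii) : std::max(mi, ii));
      double md = M_cur[j - 1] + tmd(j - 1, 0);
      double dd = D_cur[j - 1] + tdd(j - 1, 0);
      D_cur[j] = forward ? lse(md, dd) : std::max(md, dd);
    }
    std::swap(M_prev, M_cur);
    std::swap(I_prev, I_cur);
    std::swap(D_prev, D_cur);
  }
  // end: from M_m, I_m (C-terminal flank) or D_m via tmm(m,0)/tim(m,0)/tdm(m,0)
  double end_m = M_prev[m] + tmm(m, 0);
  double end_i = I_prev[m] + tim(m, 0);
  double end_d = D_prev[m] + tdm(m, 0);
  return comb(end_m, end_i, end_d);
}

// [[Rcpp::export(name = ".phmm_score_cpp")]]
NumericVector phmm_score_cpp(NumericMatrix em, List trans, List seqs,
                             bool forward) {
  NumericMatrix tmm = trans["tmm"], tmi = trans["tmi"], tmd = trans["tmd"],
                tim = trans["tim"], tii = trans["tii"], tdm = trans["tdm"],
                tdd = trans["tdd"];
  int n = seqs.size();
  NumericVector out(n);
  for (int s = 0; s < n; ++s) {
    IntegerVector sq = seqs[s];
    out[s] = phmm_dp(em, sq, tmm, tmi, tmd, tim, tii, tdm, tdd, forward);
  }
  return out;
}
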