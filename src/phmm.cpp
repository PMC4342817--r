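// Profile-HMM dynamic programming: Viterbi and forward in log-odds space.
//
// State machine (generative): N (background flank, self-loop) -> B ->
// M_k (entry distributed over match states) with M/I/D core transitions,
// any M_k (and D_k) may exit to E -> C (background flank, self-loop) ->
// terminate. Scores are natural-log odds against a null emitting every
// residue from the background; flank and ambiguous-residue emissions
// therefore contribute 0, and the caller converts to bits.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m, d;
  if (a > b) { m = a; d = b - a; } else { m = b; d = a - b; }
  if (d < -40.0) return m;  // below 4e-18 relative: vanishes at double precision
  return m + std::log1p(std::exp(d));
}

static inline double lg(double p) {
  return p > 0.0 ? std::log(p) : NEG_INF;
}

struct Model {
  int L;
  std::vector<double> lentry;          // B -> M_k
  std::vector<double> lMM, lMI, lMD, lME;
  std::vector<double> lIM, lII;
  std::vector<double> lDM, lDD, lDE;
  double lN, lNB, lC, lCT;
  std::vector<double> lMatchOdds, lInsOdds;  // L x 20, row-major
};

static Model buildModel(const NumericMatrix &matchEm,
                        const NumericMatrix &insertEm,
                        const NumericVector &entry,
                        const NumericMatrix &fromM,
                        const NumericMatrix &fromI,
                        const NumericMatrix &fromD,
                        double loopN, double loopC,
                        const NumericVector &bg) {
  Model m;
  m.L = matchEm.nrow();
  m.lentry.resize(m.L);
  m.lMM.resize(m.L); m.lMI.resize(m.L); m.lMD.resize(m.L);
  m.lME.resize(m.L);
  m.lIM.resize(m.L); m.lII.resize(m.L);
  m.lDM.resize(m.L); m.lDD.resize(m.L); m.lDE.resize(m.L);
  for (int k = 0; k < m.L; ++k) {
    m.lentry[k] = lg(entry[k]);
    m.lMM[k] = lg(fromM(k, 0)); m.lMI[k] = lg(fromM(k, 1));
    m.lMD[k] = lg(fromM(k, 2)); m.lME[k] = lg(fromM(k, 3));
    m.lIM[k] = lg(fromI(k, 0)); m.lII[k] = lg(fromI(k, 1));
    m.lDM[k] = lg(fromD(k, 0)); m.lDD[k] = lg(fromD(k, 1));
    m.lDE[k] = lg(fromD(k, 2));
  }
  m.lN = lg(loopN); m.lNB = lg(1.0 - loopN);
  m.lC = lg(loopC); m.lCT = lg(1.0 - loopC);
  m.lMatchOdds.resize(m.L * 20);
  m.lInsOdds.resize(m.L * 20);
  for (int k = 0; k < m.L; ++k)
    for (int a = 0; a < 20; ++a) {
      double b = std::log(bg[a]);
      m.lMatchOdds[k * 20 + a] =
        matchEm(k, a) > 0.0 ? std::log(matchEm(k, a)) - b : NEG_INF;
      m.lInsOdds[k * 20 + a] =
        insertEm(k, a) > 0.0 ? std::log(insertEm(k, a)) - b : NEG_INF;
    }
  return m;
}

// Emission log-odds of residue index r (1..20; 0 = ambiguous -> odds 1).
static inline double emLogOdds(const std::vector<double> &lo, int k,
                               int r) {
  if (r <= 0) return 0.0;
  return lo[k * 20 + r - 1];
}

// [[Rcpp::export(name = ".phmm_forward")]]
double phmm_forward(NumericMatrix matchEm, NumericMatrix insertEm,
                    NumericVector entry, NumericMatrix fromM,
                    NumericMatrix fromI, NumericMatrix fromD,
                    double loopN, double loopC, NumericVector bg,
                    IntegerVector seq) {
  Model m = buildModel(matchEm, insertEm, entry, fromM, fromI, fromD,
                       loopN, loopC, bg);
  const int n = seq.size(), L = m.L;
  // Row i of each DP table: prefix x_1..x_i consumed.
  std::vector<double> Mc(L, NEG_INF), Ic(L, NEG_INF), Dc(L, NEG_INF);
  std::vector<double> Mp(L, NEG_INF), Ip(L, NEG_INF), Dp(L, NEG_INF);
  double Bprev, Cprev = NEG_INF, Ccur = NEG_INF, VNi = 0.0;
  Bprev = m.lNB;  // B(0)
  for (int i = 1; i <= n; ++i) {
    int r = seq[i - 1];
    std::swap(Mc, Mp); std::swap(Ic, Ip); std::swap(Dc, Dp);
    Cprev = Ccur;
    for (int k = 0; k < L; ++k) {
      double acc = Bprev + m.lentry[k];
      if (k > 0) {
        acc = lse2(acc, Mp[k - 1] + m.lMM[k - 1]);
        acc = lse2(acc, Ip[k - 1] + m.lIM[k - 1]);
        acc = lse2(acc, Dp[k - 1] + m.lDM[k - 1]);
      }
      Mc[k] = acc + emLogOdds(m.lMatchOdds, k, r);
    }
    for (int k = 0; k < L; ++k) {
      if (k >= L - 1) { Ic[k] = NEG_INF; continue; }
      // I_k entered from M_k or I_k at the previous position.
      double acc = lse2(Mp[k] + m.lMI[k], Ip[k] + m.lII[k]);
      Ic[k] = acc + emLogOdds(m.lInsOdds, k, r);
    }
    // Delete states consume no residue: propagate within row i.
    Dc[0] = NEG_INF;  // first delete state unreachable (no B->D entry)
    for (int k = 1; k < L; ++k)
      Dc[k] = lse2(Mc[k - 1] + m.lMD[k - 1],
                   Dc[k - 1] + m.lDD[k - 1]);
    double Ei = NEG_INF;
    for (int k = 0; k < L; ++k) {
      Ei = lse2(Ei, Mc[k] + m.lME[k]);
      Ei = lse2(Ei, Dc[k] + m.lDE[k]);
    }
    VNi += m.lN;               // N(i) = i * log(loopN)
    Bprev = VNi + m.lNB;       // B(i)
    Ccur = lse2(Ei, Cprev + m.lC);
  }
  if (n == 0) return R_NegInf;
  return (Ccur + m.lCT) / std::log(2.0);
}

// [[Rcpp::export(name = ".phmm_viterbi")]]
List phmm_viterbi(NumericMatrix matchEm, NumericMatrix insertEm,
                  NumericVector entry, NumericMatrix fromM,
                  NumericMatrix fromI, NumericMatrix fromD,
                  double loopN, double loopC, NumericVector bg,
                  IntegerVector seq) {
  Model m = buildModel(matchEm, insertEm, entry, fromM, fromI, fromD,
                       loopN, loopC, bg);
  const int n = seq.size(), L = m.L;
  // DP over (i, state); states M/I/D per column plus C.
  // Backpointers: 0 = from B (entry), 1 = from M_{k-1}, 2 = from I_{k-1},
  // 3 = from D_{k-1} (for M); for I: 0 = from M_k, 1 = from I_k;
  // for D: 0 = from M_{k-1}, 1 = from D_{k-1}.
  std::vector<std::vector<double>> M(n + 1, std::vector<double>(L, NEG_INF)),
      I(n + 1, std::vector<double>(L, NEG_INF)),
      D(n + 1, std::vector<double>(L, NEG_INF));
  std::vector<std::vector<int>> bpM(n + 1, std::vector<int>(L, -1)),
      bpI(n + 1, std::vector<int>(L, -1)),
      bpD(n + 1, std::vector<int>(L, -1));
  std::vector<double> Cv(n + 1, NEG_INF), Ev(n + 1, NEG_INF);
  std::vector<int> bpC(n + 1, -1);        // 0 = from E at i, 1 = C loop
  std::vector<int> bpE(n + 1, -1);        // k>=0 from M_k, L+k from D_k
  for (int i = 1; i <= n; ++i) {
    int r = seq[i - 1];
    double Bprev = (i - 1) * m.lN + m.lNB;
    for (int k = 0; k < L; ++k) {
      double best = Bprev + m.lentry[k];
      int arg = 0;
      if (k > 0) {
        double v;
        v = M[i - 1][k - 1] + m.lMM[k - 1];
        if (v > best) { best = v; arg = 1; }
        v = I[i - 1][k - 1] + m.lIM[k - 1];
        if (v > best) { best = v; arg = 2; }
        v = D[i - 1][k - 1] + m.lDM[k - 1];
        if (v > best) { best = v; arg = 3; }
      }
      M[i][k] = best + emLogOdds(m.lMatchOdds, k, r);
      bpM[i][k] = arg;
    }
    for (int k = 0; k + 1 < L; ++k) {
      double a = M[i - 1][k] + m.lMI[k];
      double b = I[i - 1][k] + m.lII[k];
      if (a >= b) { I[i][k] = a; bpI[i][k] = 0; }
      else        { I[i][k] = b; bpI[i][k] = 1; }
      I[i][k] += emLogOdds(m.lInsOdds, k, r);
    }
    for (int k = 1; k < L; ++k) {
      double a = M[i][k - 1] + m.lMD[k - 1];
      double b = (k > 1) ? D[i][k - 1] + m.lDD[k - 1] : NEG_INF;
      if (a >= b) { D[i][k] = a; bpD[i][k] = 0; }
      else        { D[i][k] = b; bpD[i][k] = 1; }
    }
    double Ei = NEG_INF; int argE = -1;
    for (int k = 0; k < L; ++k) {
      double v = M[i][k] + m.lME[k];
      if (v > Ei) { Ei = v; argE = k; }
      v = D[i][k] + m.lDE[k];
      if (v > Ei) { Ei = v; argE = L + k; }
    }
    Ev[i] = Ei; bpE[i] = argE;
    double fromE = Ei, loopC_ = Cv[i - 1] + m.lC;
    if (fromE >= loopC_) { Cv[i] = fromE; bpC[i] = 0; }
    else                 { Cv[i] = loopC_; bpC[i] = 1; }
  }
  double score = (n > 0) ? (Cv[n] + m.lCT) / std::log(2.0) : R_NegInf;
  // Traceback: stateOf[i] (1-based positions): 0 flank, k match_k,
  // -k insert_k (k 1-based).
  IntegerVector stateOf(n, 0);
  int envStart = NA_INTEGER, envEnd = NA_INTEGER;
  if (n > 0 && std::isfinite(score)) {
    int i = n;
    while (i > 0 && bpC[i] == 1) { stateOf[i - 1] = 0; --i; }
    if (i > 0) {
      // at position i, C entered from E(i)
      int e = bpE[i];
      int k; char st;
      if (e >= L) { k = e - L; st = 'D'; } else { k = e; st = 'M'; }
      envEnd = i;
      while (true) {
        if (st == 'M') {
          stateOf[i - 1] = k + 1;
          int arg = bpM[i][k];
          if (arg == 0) { envStart = i; --i; break; }
          --i;
          if (arg == 1) { st = 'M'; k = k - 1; }
          else if (arg == 2) { st = 'I'; k = k - 1; }
          else { st = 'D'; k = k - 1; }
        } else if (st == 'I') {
          stateOf[i - 1] = -(k + 1);
          int arg = bpI[i][k];
          --i;
          st = (arg == 0) ? 'M' : 'I';
        } else {  // D consumes nothing
          int arg = bpD[i][k];
          if (arg == 0) { st = 'M'; k = k - 1; }
          else { st = 'D'; k = k - 1; }
        }
      }
      while (i > 0) { stateOf[i - 1] = 0; --i; }
    }
  }
  return List::create(_["bits"] = score, _["stateOf"] = stateOf,
                      _["envStart"] = envStart, _["envEnd"] = envEnd);
}
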