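#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Forward / Viterbi log-odds scoring of integer-encoded targets against a
// readout profile HMM.
//
// Model (glocal-query / local-target):
//   N -> B -> M1 ... core ... E -> C, with the N and C flanks emitting
//   unaligned target residues at background frequency, i.e. at odds 1 and
//   zero log-odds cost (their contributions cancel against the null model).
//   Entry is B -> M1 with probability 1; exit is M_L -> E and D_L -> E with
//   probability 1 (no leading delete, no trailing insert).  Within the
//   core, Plan7 transitions: M->M/I/D, I->M/I, D->M/D, applied uniformly at
//   every position.
// Local-query mode instead enters any match state and exits from any match
// state, uniformly over entry/exit pairs (weight 2 / (L (L + 1))).
//
// The DP runs in odds space with power-of-two rescaling: after each target
// column the cells are renormalised by 2^-e (e = exponent of the column
// maximum) and the cumulative exponent S is tracked exactly.  The begin
// state's true odds value is always 1, represented in the current scale as
// 2^-S; restart contributions more than ~2^1074 below the running scale
// underflow to zero, and upward rescaling is capped (S >= -1000) so the
// begin injection itself can never overflow.

namespace {

struct Params {
  double tMM, tMI, tMD, tIM, tII, tDM, tDD;
};

inline double max3(double a, double b, double c) {
  return std::max(a, std::max(b, c));
}

// flush-to-zero threshold: cells this far below the working scale are
// irrelevant to sum and max alike, and letting them decay into subnormals
// costs an order of magnitude in throughput
const double kTiny = 1e-290;

inline double ftz(double v) { return v > kTiny ? v : 0.0; }

// one pass over one target; viterbi == false gives Forward (sum), true
// gives Viterbi (max).  Returns log2-odds (bits), -Inf if no path.
double scoreOne(const std::vector<double>& eo, int Lq, const Params& p,
                const int* t, int Lt, bool viterbi, bool localQuery) {
  const double w = localQuery ? 2.0 / (double(Lq) * double(Lq + 1)) : 0.0;
  std::vector<double> Mp(Lq + 1, 0.0), Ip(Lq + 1, 0.0), Dp(Lq + 1, 0.0);
  std::vector<double> Mc(Lq + 1, 0.0), Ic(Lq + 1, 0.0), Dc(Lq + 1, 0.0);
  long S = 0;       // cumulative power-of-two scale
  double acc = 0.0; // forward sum / viterbi max over end positions

  for (int j = 0; j < Lt; ++j) {
    const double* eoa = &eo[size_t(t[j]) * Lq];
    const double B = std::ldexp(1.0, int(-S > 1000 ? 1000 : -S));
    double colmax = 0.0;

    if (viterbi) {
      Mc[1] = ftz(eoa[0] * max3(p.tMM * Mp[0], p.tIM * Ip[0],
                            max3(p.tDM * Dp[0], localQuery ? w * B : B, 0.0)));
      for (int k = 2; k <= Lq; ++k) {
        double best = max3(p.tMM * Mp[k - 1], p.tIM * Ip[k - 1],
                           p.tDM * Dp[k - 1]);
        if (localQuery && w * B > best) best = w * B;
        Mc[k] = ftz(eoa[k - 1] * best);
      }
      for (int k = 1; k < Lq; ++k) {
        Ic[k] = ftz(std::max(p.tMI * Mp[k], p.tII * Ip[k]));
      }
      Dc[1] = 0.0;
      for (int k = 2; k <= Lq; ++k) {
        Dc[k] = ftz(std::max(p.tMD * Mc[k - 1], p.tDD * Dc[k - 1]));
      }
      double E;
      if (localQuery) {
        E = 0.0;
        for (int k = 1; k <= Lq; ++k) E = std::max(E, Mc[k]);
      } else {
        E = std::max(Mc[Lq], Dc[Lq]);
      }
      if (E > acc) acc = E;
      for (int k = 1; k <= Lq; ++k) {
        if (Mc[k] > colmax) colmax = Mc[k];
      }
    } else {
      const double entry1 = (localQuery ? w : 1.0) * B;
      const double entryK = localQuery ? w * B : 0.0;
      Mc[1] = ftz(eoa[0] * (p.tMM * Mp[0] + p.tIM * Ip[0] + p.tDM * Dp[0] +
                        entry1));
      Ic[1] = ftz(p.tMI * Mp[1] + p.tII * Ip[1]);
      Dc[1] = 0.0;
      double d = 0.0; // running delete chain (serial dependency kept local)
      for (int k = 2; k <= Lq; ++k) {
        const double mprev = Mc[k - 1];
        Mc[k] = ftz(eoa[k - 1] *
          (p.tMM * Mp[k - 1] + p.tIM * Ip[k - 1] + p.tDM * Dp[k - 1] +
           entryK));
        Ic[k] = ftz(p.tMI * Mp[k] + p.tII * Ip[k]);
        d = ftz(p.tMD * mprev + p.tDD * d);
        Dc[k] = d;
      }
      if (Lq >= 1) Ic[Lq] = 0.0; // no trailing insert state
      double E;
      if (localQuery) {
        E = 0.0;
        for (int k = 1; k <= Lq; ++k) E += Mc[k];
      } else {
        E = Mc[Lq] + Dc[Lq];
      }
      acc += E;
    }

    // rescale when the dynamic range drifts too far from 1; checked every
    // 8th column (per-column drift is bounded by the largest emission odds,
    // so the band cannot be overshot between checks)
    if (!viterbi && (j & 7) == 7) {
      colmax = 0.0;
      for (int k = 1; k <= Lq; ++k) {
        if (Mc[k] > colmax) colmax = Mc[k];
      }
    }
    if (colmax > 0.0 && (colmax > 1e120 || colmax < 1e-120)) {
      int e = std::ilogb(colmax);
      if (S + e < -1000) e = int(-1000 - S);
      if (e != 0) {
        const double c = std::ldexp(1.0, -e);
        for (int k = 0; k <= Lq; ++k) {
          Mc[k] *= c; Ic[k] *= c; Dc[k] *= c;
        }
        acc *= c;
        S += e;
      }
    }
    Mp.swap(Mc);
    Ip.swap(Ic);
    Dp.swap(Dc);
  }
  if (acc <= 0.0) return R_NegInf;
  return std::log2(acc) + double(S);
}

} // namespace

// [[Rcpp::export]]
NumericMatrix scoreTargetsCpp(NumericMatrix emissions, NumericVector bg,
                              NumericVector trans, List targets,
                              bool doForward, bool doViterbi,
                              bool localQuery) {
  const int Lq = emissions.ncol();
  if (emissions.nrow() != 20 || bg.size() != 20 || trans.size() != 7) {
    stop("malformed profile inputs");
  }
  Params p = {trans[0], trans[1], trans[2], trans[3], trans[4], trans[5],
              trans[6]};
  // emission odds, laid out residue-major so eo[a * Lq + k] is contiguous
  // over match positions
  std::vector<double> eo(size_t(20) * Lq);
  for (int a = 0; a < 20; ++a) {
    for (int k = 0; k < Lq; ++k) {
      eo[size_t(a) * Lq + k] = bg[a] > 0.0 ? emissions(a, k) / bg[a] : 0.0;
    }
  }
  const int nT = targets.size();
  NumericMatrix out(nT, 2);
  for (int i = 0; i < nT; ++i) {
    IntegerVector tv = targets[i];
    if (tv.size() == 0) stop("empty target sequence");
    for (int j = 0; j < tv.size(); ++j) {
      if (tv[j] < 0 || tv[j] >= 20) stop("target residue code out of range");
    }
    out(i, 0) = doForward
      ? scoreOne(eo, Lq, p, tv.begin(), tv.size(), false, localQuery)
      : NA_REAL;
    out(i, 1) = doViterbi
      ? scoreOne(eo, Lq, p, tv.begin(), tv.size(), true, localQuery)
      : NA_REAL;
  }
  return out;
}
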