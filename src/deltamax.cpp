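#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

// Exact maximization of the Das-Pappu blob-wise charge asymmetry deviation
// (delta) over all arrangements of a fixed composition.
//
// delta(seq, g) = mean over all fully contained length-g windows of
// (sigma_win - sigma_seq)^2, with sigma = (f+ - f-)^2 / (f+ + f-) and
// sigma = 0 for windows without charged residues. sigma_seq depends only on
// the composition, so maximizing delta over permutations is a sequential
// decision problem: place residues left to right; a window's contribution
// is determined by the last g letters. The DP state is the exact tuple of
// the last g-1 placed letters (base-3 code; leading zeros behave as
// neutral padding and are never scored because windows only complete once
// g letters exist) together with the number of +/- residues used so far.

static inline double sigma_frac(double fp, double fm) {
  double den = fp + fm;
  if (den == 0.0) return 0.0;
  double d = fp - fm;
  return d * d / den;
}

// [[Rcpp::export]]
double dmax_exact_cpp(int p, int m, int z, int g) {
  const int n = p + m + z;
  if (g < 2 || n < g) Rcpp::stop("need blob >= 2 and length >= blob");
  if (p + m == 0) return 0.0;

  int S = 1;
  for (int k = 0; k < g - 1; ++k) S *= 3;

  // per-state counts of + (digit 1) and - (digit 2)
  std::vector<unsigned char> cntP(S, 0), cntM(S, 0);
  for (int s = 0; s < S; ++s) {
    int t = s, cp = 0, cm = 0;
    for (int k = 0; k < g - 1; ++k) {
      int d = t % 3;
      t /= 3;
      if (d == 1) ++cp;
      else if (d == 2) ++cm;
    }
    cntP[s] = (unsigned char)cp;
    cntM[s] = (unsigned char)cm;
  }

  const double sg = sigma_frac((double)p / n, (double)m / n);
  // contribution lookup by window (+,-) counts
  std::vector<double> contrib((g + 1) * (g + 1));
  for (int wp = 0; wp <= g; ++wp) {
    for (int wm = 0; wm + wp <= g; ++wm) {
      double d = sigma_frac((double)wp / g, (double)wm / g) - sg;
      contrib[wp * (g + 1) + wm] = d * d;
    }
  }

  const double NEG = -std::numeric_limits<double>::infinity();
  const size_t P1 = (size_t)p + 1, M1 = (size_t)m + 1;
  const size_t NS = (size_t)S * P1 * M1;
  std::vector<double> cur(NS, NEG), nxt(NS, NEG);
  cur[0] = 0.0; // state 0, 0 used of each charge

  for (int i = 0; i < n; ++i) {
    std::fill(nxt.begin(), nxt.end(), NEG);
    const bool scoring = (i + 1 >= g);
    for (int s = 0; s < S; ++s) {
      const size_t base_s = (size_t)s * P1 * M1;
      const int ns0 = (s * 3) % S;
      for (size_t a = 0; a <= (size_t)p; ++a) {
        for (size_t b = 0; b <= (size_t)m; ++b) {
          const double v = cur[base_s + a * M1 + b];
          if (v == NEG) continue;
          const int used0 = i - (int)a - (int)b; // neutrals placed so far
          // place neutral
          if (used0 < z) {
            double w = v;
            if (scoring) w += contrib[cntP[s] * (g + 1) + cntM[s]];
            double *slot = &nxt[(size_t)ns0 * P1 * M1 + a * M1 + b];
            if (w > *slot) *slot = w;
          }
          // place positive
          if (a < (size_t)p) {
            double w = v;
            if (scoring) w += contrib[(cntP[s] + 1) * (g + 1) + cntM[s]];
            double *slot = &nxt[(size_t)(ns0 + 1) * P1 * M1 + (a + 1) * M1 + b];
            if (w > *slot) *slot = w;
          }
          // place negative
          if (b < (size_t)m) {
            double w = v;
            if (scoring) w += contrib[cntP[s] * (g + 1) + cntM[s] + 1];
            double *slot = &nxt[(size_t)(ns0 + 2) * P1 * M1 + a * M1 + (b + 1)];
            if (w > *slot) *slot = w;
          }
        }
      }
    }
    cur.swap(nxt);
  }

  double best = NEG;
  // only states with the full composition used are reachable here
  for (int s = 0; s < S; ++s) {
    double v = cur[(size_t)s * P1 * M1 + (size_t)p * M1 + (size_t)m];
    if (v > best) best = v;
  }
  return best / (double)(n - g + 1);
}
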