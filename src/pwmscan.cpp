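#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline int encode_dna(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': case 'U': case 'u': return 3;
  default: return -1;
  }
}

// Scan one strand of a promoter with an information-weighted PWM.
// w is a 4 x L matrix of Ci * p(i, b) weights (rows A,C,G,T); a window's
// matrix similarity is sum_i w[base_i, i] / sum_i max_b w[b, i], and the
// core similarity is the same ratio over the 1-based positions in `core`.
// Windows containing non-ACGT characters are skipped. Returns a matrix with
// columns (offset, core_sim, matrix_sim) for windows passing both
// thresholds; offsets are 1-based window starts.
// [[Rcpp::export]]
NumericMatrix pwm_scan_cpp(std::string seq, NumericMatrix w,
                           IntegerVector core, double core_threshold,
                           double matrix_threshold) {
  int L = w.ncol();
  int n = (int) seq.size();
  // flat copies: wf[5*i + b] full weight, cf[5*i + b] core-masked weight;
  // slot b = 4 (non-ACGT) carries -1e30 so N windows can never pass
  std::vector<double> wf(5 * L), cf(5 * L);
  double denom = 0.0, core_denom = 0.0;
  std::vector<bool> in_core(L, false);
  for (int k = 0; k < core.size(); ++k) in_core[core[k] - 1] = true;
  for (int i = 0; i < L; ++i) {
    double m = w(0, i);
    for (int b = 1; b < 4; ++b) if (w(b, i) > m) m = w(b, i);
    denom += m;
    if (in_core[i]) core_denom += m;
    for (int b = 0; b < 4; ++b) {
      wf[5 * i + b] = w(b, i);
      cf[5 * i + b] = in_core[i] ? w(b, i) : 0.0;
    }
    wf[5 * i + 4] = -1e30;
    cf[5 * i + 4] = 0.0;
  }
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) {
    int b = encode_dna(seq[i]);
    s[i] = (b < 0) ? 4 : b;
  }

  std::vector<double> off, cs, ms;
  if (denom <= 0.0) {  // fully degenerate PWM: every window scores 0
    return NumericMatrix(0, 3);
  }
  double min_num = matrix_threshold * denom;
  const int *sp = s.data();
  const double *wp = wf.data(), *cp = cf.data();
  for (int o = 0; o + L <= n; ++o) {
    double num = 0.0;
    for (int i = 0; i < L; ++i) num += wp[5 * i + sp[o + i]];
    if (num < min_num) continue;
    double core_num = 0.0;
    for (int i = 0; i < L; ++i) core_num += cp[5 * i + sp[o + i]];
    double msim = num / denom;
    double csim = core_denom > 0.0 ? core_num / core_denom : 0.0;
    if (msim >= matrix_threshold && csim >= core_threshold) {
      off.push_back(o + 1);
      cs.push_back(csim);
      ms.push_back(msim);
    }
  }
  NumericMatrix out((int) off.size(), 3);
  for (int r = 0; r < (int) off.size(); ++r) {
    out(r, 0) = off[r];
    out(r, 1) = cs[r];
    out(r, 2) = ms[r];
  }
  return out;
}
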