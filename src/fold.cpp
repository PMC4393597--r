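#include <Rcpp.h>
#include <vector>
#include <stack>
using namespace Rcpp;

// RNA base encoding: A=0, C=1, G=2, U/T=3, anything else = -1
static inline int encode_base(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'U': case 'u': case 'T': case 't': return 3;
  default: return -1;
  }
}

// Watson-Crick + GU wobble
static inline bool can_pair(int a, int b) {
  if (a < 0 || b < 0) return false;
  int lo = a < b ? a : b, hi = a < b ? b : a;
  return (lo == 0 && hi == 3) ||  // A-U
         (lo == 1 && hi == 2) ||  // C-G
         (lo == 2 && hi == 3);    // G-U
}

// Maximum base-pairing (Nussinov-style) with minimum hairpin loop length.
// Traceback is deterministic: for interval [i, j], if some k pairs with j
// and achieves the optimum, the smallest such k is chosen (5'-most
// pairing); otherwise j is left unpaired.
// [[Rcpp::export]]
List fold_maxpair_cpp(std::string seq, int min_loop) {
  int n = (int) seq.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) {
    s[i] = encode_base(seq[i]);
    if (s[i] < 0) stop("fold: sequence contains a non-ACGU(T) character");
  }
  if (n == 0)
    return List::create(_["structure"] = "", _["pair_count"] = 0,
                        _["pairs"] = IntegerMatrix(0, 2));

  // N[i][j] = max pairs in s[i..j], 0-based inclusive
  std::vector<std::vector<int> > N(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = N[i][j - 1];  // j unpaired
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (!can_pair(s[k], s[j])) continue;
        int left = (k > i) ? N[i][k - 1] : 0;
        int inner = (k + 1 <= j - 1) ? N[k + 1][j - 1] : 0;
        int cand = left + inner + 1;
        if (cand > best) best = cand;
      }
      N[i][j] = best;
    }
  }

  // traceback
  std::vector<int> partner(n, -1);
  std::stack<std::pair<int, int> > st;
  st.push(std::make_pair(0, n - 1));
  while (!st.empty()) {
    std::pair<int, int> iv = st.top(); st.pop();
    int i = iv.first, j = iv.second;
    if (i >= j || j - i < min_loop + 1) continue;
    int target = N[i][j];
    if (target == 0) continue;
    bool done = false;
    for (int k = i; k <= j - min_loop - 1 && !done; ++k) {
      if (!can_pair(s[k], s[j])) continue;
      int left = (k > i) ? N[i][k - 1] : 0;
      int inner = (k + 1 <= j - 1) ? N[k + 1][j - 1] : 0;
      if (left + inner + 1 == target) {
        partner[k] = j; partner[j] = k;
        if (k > i) st.push(std::make_pair(i, k - 1));
        if (k + 1 <= j - 1) st.push(std::make_pair(k + 1, j - 1));
        done = true;
      }
    }
    if (!done) st.push(std::make_pair(i, j - 1));  // j unpaired
  }

  int np = 0;
  for (int i = 0; i < n; ++i) if (partner[i] > i) ++np;
  IntegerMatrix pairs(np, 2);
  std::string db(n, '.');
  int r = 0;
  for (int i = 0; i < n; ++i) {
    if (partner[i] > i) {
      pairs(r, 0) = i + 1;           // 1-based
      pairs(r, 1) = partner[i] + 1;
      db[i] = '(';
      db[partner[i]] = ')';
      ++r;
    }
  }
  return List::create(_["structure"] = db,
                      _["pair_count"] = N[0][n - 1],
                      _["pairs"] = pairs);
}
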