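#include <Rcpp.h>
using namespace Rcpp;

// Global Needleman-Wunsch with match +1, mismatch 0, linear gap -1.
// Ties broken diagonal > up > left so the reported identity is deterministic.
// Sequences arrive as 0-based integer codes (20 = X); equal codes count as a
// match, including X/X.
// [[Rcpp::export]]
List nw_identity_cpp(IntegerVector a, IntegerVector b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence in pairwise alignment");
  std::vector<int> score((n + 1) * (m + 1));
  std::vector<unsigned char> tb((n + 1) * (m + 1)); // 0 diag, 1 up, 2 left
  const int W = m + 1;
  for (int i = 0; i <= n; ++i) { score[i * W] = -i; tb[i * W] = 1; }
  for (int j = 0; j <= m; ++j) { score[j] = -j; tb[j] = 2; }
  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int diag = score[(i - 1) * W + (j - 1)] + (ai == b[j - 1] ? 1 : 0);
      const int up = score[(i - 1) * W + j] - 1;
      const int left = score[i * W + (j - 1)] - 1;
      int best = diag; unsigned char dir = 0;
      if (up > best) { best = up; dir = 1; }
      if (left > best) { best = left; dir = 2; }
      score[i * W + j] = best;
      tb[i * W + j] = dir;
    }
  }
  int i = n, j = m, matches = 0, alen = 0;
  while (i > 0 || j > 0) {
    const unsigned char dir = tb[i * W + j];
    if (dir == 0 && i > 0 && j > 0) {
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (dir == 1 && i > 0) {
      --i;
    } else {
      --j;
    }
    ++alen;
  }
  return List::create(_["identity"] = alen > 0 ? (double)matches / alen : 0.0,
                      _["matches"] = matches,
                      _["alignment_length"] = alen,
                      _["score"] = score[n * W + m]);
}

// Best ungapped window of a position-specific log-odds matrix over a coded
// sequence. Leftmost window wins ties. Returns NULL when the sequence is
// shorter than the profile.
// [[Rcpp::export]]
SEXP scan_best_cpp(NumericMatrix log_odds, IntegerVector seq) {
  const int L = log_odds.nrow();
  const int n = seq.size();
  if (n < L) return R_NilValue;
  double best = R_NegInf;
  int best_off = 0;
  for (int off = 0; off + L <= n; ++off) {
    double sc = 0.0;
    for (int i = 0; i < L; ++i) sc += log_odds(i, seq[off + i]);
    if (sc > best) { best = sc; best_off = off; }
  }
  return List::create(_["bitscore"] = best, _["window_start"] = best_off,
                      _["window_end"] = best_off + L);
}
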