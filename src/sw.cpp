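#include <Rcpp.h>
using namespace Rcpp;

// Direction codes shared with the R traceback walker.
static const int DIR_STOP = 0;
static const int DIR_DIAG = 1;
static const int DIR_UP   = 2;   // consumes a read base (gap in window)
static const int DIR_LEFT = 3;   // consumes a window base (gap in read)

// conversion modes: 0 = none, 1 = c_to_t, 2 = g_to_a
static inline int subst(char a, char b, int match, int mismatch, int mode) {
  if (a == 'N' || b == 'N') return mismatch;   // N never matches
  if (a == b) return match;
  if (mode == 1 && a == 'T' && b == 'C') return match;  // converted cytosine
  if (mode == 2 && a == 'A' && b == 'G') return match;  // opposite-strand read
  return mismatch;
}

static inline void check_alphabet(const std::string& s, const char* what) {
  for (size_t k = 0; k < s.size(); ++k) {
    char c = s[k];
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T' && c != 'N')
      stop("illegal base '%s' in %s at position %d (alphabet is A/C/G/T/N)",
           std::string(1, c).c_str(), what, (int)(k + 1));
  }
}

// Smith-Waterman fill with linear gaps, zero floor, and per-cell recording of
// the source direction that attained the maximum (tie order
// DIAG > UP > LEFT > STOP; STOP iff the cell score is zero). The argmax is
// the first maximal cell in row-major order.
// [[Rcpp::export(name = ".sw_fill")]]
List sw_fill(std::string read, std::string window,
             int match, int mismatch, int gap, int mode) {
  int n = read.size(), m = window.size();
  if (n == 0 || m == 0) stop("read and window must be non-empty");
  check_alphabet(read, "read");
  check_alphabet(window, "window");

  IntegerMatrix H(n + 1, m + 1);
  IntegerMatrix D(n + 1, m + 1);   // initialised to 0 == STOP
  int best = 0, best_i = 0, best_j = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int s   = subst(read[i - 1], window[j - 1], match, mismatch, mode);
      int dg  = H(i - 1, j - 1) + s;
      int up  = H(i - 1, j) + gap;
      int lf  = H(i, j - 1) + gap;
      int h   = dg;
      int dir = DIR_DIAG;
      if (up > h) { h = up; dir = DIR_UP; }
      if (lf > h) { h = lf; dir = DIR_LEFT; }
      if (h <= 0) { h = 0; dir = DIR_STOP; }
      H(i, j) = h;
      D(i, j) = dir;
      // row-major first maximum: strict improvement only
      if (h > best) { best = h; best_i = i; best_j = j; }
    }
  }
  return List::create(_["score"] = H, _["direction"] = D,
                      _["argmax"] = IntegerVector::create(best_i, best_j),
                      _["max_score"] = best);
}
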