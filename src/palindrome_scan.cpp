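#include <Rcpp.h>
using namespace Rcpp;

// Watson-Crick complement; anything outside A/C/G/T (incl. N) never pairs.
static inline char wc(char b) {
  switch (b) {
    case 'A': return 'T';
    case 'T': return 'A';
    case 'C': return 'G';
    case 'G': return 'C';
    default:  return '\0';
  }
}

// Exact inverted-repeat scan by centre expansion.
//
// For every candidate loop (gap) of length 0..max_loop the arms are grown
// outward while the outer pair is reverse-complementary, so every reported
// structure is outward-maximal by construction.  A centre whose innermost
// gap flanks still pair is skipped: the same interval is found (with a
// longer arm and loop - 2) from the deeper centre, so each reported
// (start, end) carries its maximal arm / minimal loop decomposition.
//
// Returns a 4-column integer matrix: start, end, arm_len, loop_len
// (1-based inclusive coordinates).
// [[Rcpp::export(name = ".scan_palindromes_cpp")]]
IntegerMatrix scan_palindromes_cpp(std::string seq, int min_len, int min_arm,
                                   int max_loop) {
  const int n = static_cast<int>(seq.size());
  std::vector<int> st, en, arm, loop;
  for (int l = 0; l <= max_loop; ++l) {
    for (int p = 1; p + l < n; ++p) {  // gap occupies [p, p + l - 1], 0-based
      if (l >= 2) {
        char inner = wc(seq[p]);
        if (inner != '\0' && inner == seq[p + l - 1]) continue;
      }
      int i = p - 1, j = p + l, a = 0;
      while (i >= 0 && j < n) {
        char c = wc(seq[i]);
        if (c == '\0' || c != seq[j]) break;
        ++a; --i; ++j;
      }
      if (a >= min_arm && 2 * a + l >= min_len) {
        st.push_back(i + 2);  // i sits one before the start (0-based)
        en.push_back(j);      // j sits one past the end (0-based)
        arm.push_back(a);
        loop.push_back(l);
      }
    }
  }
  const int m = static_cast<int>(st.size());
  IntegerMatrix out(m, 4);
  for (int k = 0; k < m; ++k) {
    out(k, 0) = st[k];
    out(k, 1) = en[k];
    out(k, 2) = arm[k];
    out(k, 3) = loop[k];
  }
  colnames(out) = CharacterVector::create("start", "end", "arm_len", "loop_len");
  return out;
}
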