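#include <Rcpp.h>
#include <vector>
#include <string>

// Ends-free (semi-global) pairwise alignment with linear gap costs.
//
// Dynamic programme over lexicographic value (score, matches, -columns):
// among all alignments we maximize the alignment score; among co-optimal
// alignments we maximize the number of identical aligned bases, then
// minimize the number of alignment columns. Lexicographic optimization with
// additive per-step rewards satisfies the usual optimal-substructure
// argument, so the triple at each cell is well defined and the reported
// percent identity is canonical (independent of traceback order).
//
// Terminal overhangs are free and excluded from the identity denominator:
// the DP starts anywhere in the first row/column and ends anywhere in the
// last row/column. Only exact A/C/G/T base matches count as matches; IUPAC
// ambiguity codes always score as mismatches.

struct Cell {
  double score;
  int matches;
  int cols;
};

static inline bool lex_better(const Cell &a, const Cell &b) {
  if (a.score != b.score) return a.score > b.score;
  if (a.matches != b.matches) return a.matches > b.matches;
  return a.cols < b.cols;
}

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// [[Rcpp::export(name = ".align_endsfree")]]
Rcpp::List align_endsfree(std::string a, std::string b,
                          double match, double mismatch, double gap) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) Rcpp::stop("empty sequence");

  std::vector<Cell> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = {0.0, 0, 0};  // free leading overhang

  Cell best = {match * -1e18, 0, 0};
  bool have_best = false;
  for (int i = 1; i <= n; ++i) {
    cur[0] = {0.0, 0, 0};
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const char bj = b[j - 1];
      const bool eq = (ai == bj) && is_acgt(ai);
      Cell d = {prev[j - 1].score + (eq ? match : mismatch),
                prev[j - 1].matches + (eq ? 1 : 0),
                prev[j - 1].cols + 1};
      Cell u = {prev[j].score + gap, prev[j].matches, prev[j].cols + 1};
      Cell l = {cur[j - 1].score + gap, cur[j - 1].matches, cur[j - 1].cols + 1};
      Cell v = d;
      if (lex_better(u, v)) v = u;
      if (lex_better(l, v)) v = l;
      cur[j] = v;
    }
    // candidate alignment end: last column (trailing overhang of b is empty,
    // trailing overhang of a is rows i+1..n)
    if (!have_best || lex_better(cur[m], best)) { best = cur[m]; have_best = true; }
    std::swap(prev, cur);
  }
  // last row: trailing overhang of b
  for (int j = 0; j <= m; ++j) {
    if (!have_best || lex_better(prev[j], best)) { best = prev[j]; have_best = true; }
  }
  double pid = best.cols > 0 ? 100.0 * (double)best.matches / (double)best.cols : 0.0;
  return Rcpp::List::create(Rcpp::Named("score") = best.score,
                            Rcpp::Named("matches") = best.matches,
                            Rcpp::Named("columns") = best.cols,
                            Rcpp::Named("percent_identity") = pid);
}
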