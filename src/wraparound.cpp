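#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
using namespace Rcpp;

// Wraparound dynamic programming of a sequence against a cyclic pattern.
//
// State W[i][j]: best score of an alignment of seq[1..i] whose last consumed
// pattern column is j (columns cycle, so copies of the pattern may be crossed
// any number of times).  Moves:
//   diagonal: consume seq char i at pattern column j  (match/mismatch)
//   up:       consume seq char i with no pattern column (insertion in seq)
//   left:     skip pattern column j (deletion), no seq char consumed
// The left move wraps within a row (cyclic dependency); because the indel
// penalty is strictly positive the recurrence reaches a fixed point after a
// small number of in-row sweeps.
//
// Start is free in phase (W[0][j] = 0 for all j); the score is max_j W[n][j],
// i.e. a global alignment of the whole sequence against tandem repetitions of
// the pattern with free start/end phase.

// [[Rcpp::export]]
List wrap_dp_cpp(std::string seq, std::string pat,
                 int match_w, int mismatch_p, int indel_p) {
  const int n = seq.size(), p = pat.size();
  if (p < 1) stop("empty pattern");
  if (n < 1) stop("empty sequence");
  if ((double)(n + 1) * p > 6e7) stop("sequence x pattern too large for wraparound DP");
  const int NEG = INT_MIN / 4;

  std::vector<int> Wprev(p), Wcur(p);
  // full DP matrix kept for traceback
  std::vector<int> W((size_t)(n + 1) * p);
  for (int j = 0; j < p; ++j) W[j] = 0;

  for (int i = 1; i <= n; ++i) {
    const int *prev = &W[(size_t)(i - 1) * p];
    int *cur = &W[(size_t)i * p];
    for (int j = 0; j < p; ++j) cur[j] = NEG;
    char sc = seq[i - 1];
    bool changed = true;
    int sweep = 0;
    while (changed && sweep < 4) {
      changed = false;
      ++sweep;
      for (int j = 0; j < p; ++j) {
        int jm1 = (j - 1 + p) % p;
        int sub = (sc == pat[j]) ? match_w : -mismatch_p;
        int best = prev[jm1] + sub;              // diagonal
        int up = prev[j] - indel_p;              // insertion in seq
        if (up > best) best = up;
        int left = cur[jm1] > NEG ? cur[jm1] - indel_p : NEG;  // deletion
        if (left > best) best = left;
        if (best > cur[j]) { cur[j] = best; changed = true; }
      }
    }
  }

  // end cell: max over last row, smallest j on ties
  const int *last = &W[(size_t)n * p];
  int jbest = 0;
  for (int j = 1; j < p; ++j) if (last[j] > last[jbest]) jbest = j;
  int score = last[jbest];

  // traceback; priority diagonal > left > up for determinism
  IntegerVector col_of_seq(n);  // 1-based pattern column, 0 = insertion
  int matches = 0, mismatches = 0, indels = 0, columns = 0;
  int i = n, j = jbest;
  while (i > 0) {
    const int *cur = &W[(size_t)i * p];
    const int *prev = &W[(size_t)(i - 1) * p];
    int jm1 = (j - 1 + p) % p;
    int sub = (seq[i - 1] == pat[j]) ? match_w : -mismatch_p;
    if (cur[j] == prev[jm1] + sub) {
      col_of_seq[i - 1] = j + 1;
      if (seq[i - 1] == pat[j]) ++matches; else ++mismatches;
      ++columns;
      --i; j = jm1;
    } else if (cur[jm1] > NEG && cur[j] == cur[jm1] - indel_p) {
      ++indels; ++columns;  // pattern column skipped
      j = jm1;
    } else if (cur[j] == prev[j] - indel_p) {
      col_of_seq[i - 1] = 0;
      ++indels; ++columns;  // seq char inserted
      --i;
    } else {
      stop("wraparound traceback failed (internal error)");
    }
  }

  return List::create(_["score"] = score,
                      _["matches"] = matches,
                      _["mismatches"] = mismatches,
                      _["indels"] = indels,
                      _["columns"] = columns,
                      _["col_of_seq"] = col_of_seq);
}

// Maximal exact shared substrings between two strings (linear, not circular;
// circular doubling is done by the caller).  Returns runs of length >= min_len
// on the main diagonals; maximality is per diagonal (not extendable either
// side).  Coordinates are 1-based starts in a and b.

// [[Rcpp::export]]
DataFrame max_shared_substrings_cpp(std::string a, std::string b, int min_len) {
  int na = a.size(), nb = b.size();
  std::vector<int> sa, sb, ln;
  for (int d = -(na - 1); d <= nb - 1; ++d) {
    // diagonal: a[i] vs b[i + d]
    int i0 = std::max(0, -d);
    int i1 = std::min(na - 1, nb - 1 - d);
    int run = 0;
    for (int i = i0; i <= i1; ++i) {
      if (a[i] == b[i + d]) {
        ++run;
      } else {
        if (run >= min_len) { sa.push_back(i - run + 1); sb.push_back(i - run + d + 1); ln.push_back(run); }
        run = 0;
      }
    }
    if (run >= min_len) { sa.push_back(i1 - run + 2); sb.push_back(i1 - run + d + 2); ln.push_back(run); }
  }
  return DataFrame::create(_["a_start"] = sa, _["b_start"] = sb, _["length"] = ln);
}
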