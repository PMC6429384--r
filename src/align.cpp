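#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman local alignment with linear gap penalty; returns the score
// and identity/span statistics of the best local alignment.

// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b,
                  double match = 1, double mismatch = -2, double gap = -3) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0.0, _["matches"] = 0, _["columns"] = 0,
                        _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0);
  std::vector<double> prev(m + 1, 0.0), cur(m + 1, 0.0);
  // traceback directions: 0 stop, 1 diag, 2 up (gap in b), 3 left (gap in a)
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1), 0);
  double best = 0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0;
    for (int j = 1; j <= m; ++j) {
      double d = prev[j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
      double u = prev[j] + gap;
      double l = cur[j - 1] + gap;
      double v = d; unsigned char t = 1;
      if (u > v) { v = u; t = 2; }
      if (l > v) { v = l; t = 3; }
      if (v <= 0) { v = 0; t = 0; }
      cur[j] = v;
      tb[(size_t)i * (m + 1) + j] = t;
      if (v > best) { best = v; bi = i; bj = j; }
    }
    std::swap(prev, cur);
  }
  int matches = 0, columns = 0;
  int i = bi, j = bj;
  while (i > 0 && j > 0) {
    unsigned char t = tb[(size_t)i * (m + 1) + j];
    if (t == 0) break;
    ++columns;
    if (t == 1) {
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (t == 2) {
      --i;
    } else {
      --j;
    }
  }
  return List::create(_["score"] = best, _["matches"] = matches,
                      _["columns"] = columns,
                      _["a_start"] = i + 1, _["a_end"] = bi,
                      _["b_start"] = j + 1, _["b_end"] = bj);
}

// Needleman-Wunsch global alignment (linear gaps, end gaps penalized);
// returns identity over all alignment columns.

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match = 1, double mismatch = -2, double gap = -3) {
  const int n = a.size(), m = b.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1), 0);
  for (int j = 0; j <= m; ++j) { prev[j] = j * gap; tb[j] = 3; }
  tb[0] = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;
    tb[(size_t)i * (m + 1)] = 2;
    for (int j = 1; j <= m; ++j) {
      double d = prev[j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
      double u = prev[j] + gap;
      double l = cur[j - 1] + gap;
      double v = d; unsigned char t = 1;
      if (u > v) { v = u; t = 2; }
      if (l > v) { v = l; t = 3; }
      cur[j] = v;
      tb[(size_t)i * (m + 1) + j] = t;
    }
    std::swap(prev, cur);
  }
  int matches = 0, columns = 0;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char t = tb[(size_t)i * (m + 1) + j];
    ++columns;
    if (t == 1) { if (a[i - 1] == b[j - 1]) ++matches; --i; --j; }
    else if (t == 2) --i;
    else --j;
  }
  return List::create(_["score"] = prev[m], _["matches"] = matches,
                      _["columns"] = columns);
}
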