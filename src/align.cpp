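#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Dynamic-programming pairwise alignment under a linear gap scheme.
// Tie-breaking during traceback is fixed as diagonal > up (gap in b) > left
// (gap in a) so results are fully deterministic.

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  // traceback codes: 0 diag, 1 up (consume a), 2 left (consume b)
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1));
  for (int j = 0; j <= m; ++j) { prev[j] = j * gap; tb[j] = 2; }
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;
    tb[(size_t)i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      double sdiag = prev[j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
      double sup = prev[j] + gap;
      double sleft = cur[j - 1] + gap;
      double best = sdiag; unsigned char code = 0;
      if (sup > best) { best = sup; code = 1; }
      if (sleft > best) { best = sleft; code = 2; }
      cur[j] = best;
      tb[(size_t)i * (m + 1) + j] = code;
    }
    std::swap(prev, cur);
  }
  double score = prev[m];
  std::string ga, gb;
  ga.reserve(n + m); gb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char code = tb[(size_t)i * (m + 1) + j];
    if (i > 0 && j > 0 && code == 0) {
      ga.push_back(a[--i]);
      gb.push_back(b[--j]);
    } else if (i > 0 && (j == 0 || code == 1)) {
      ga.push_back(a[--i]); gb.push_back('-');
    } else {
      ga.push_back('-'); gb.push_back(b[--j]);
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return List::create(_["aligned_a"] = ga, _["aligned_b"] = gb,
                      _["score"] = score);
}

// Local (Smith-Waterman) alignment; returns the single best-scoring local
// alignment. Ties are resolved toward the cell reached first in row-major
// order (smallest end position in a, then in b), and traceback prefers
// diagonal > up > left. Start/end positions are 0-based half-open.

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  std::vector<double> prev(m + 1, 0.0), cur(m + 1, 0.0);
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1), 3); // 3 = stop
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      double sdiag = prev[j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
      double sup = prev[j] + gap;
      double sleft = cur[j - 1] + gap;
      double v = sdiag; unsigned char code = 0;
      if (sup > v) { v = sup; code = 1; }
      if (sleft > v) { v = sleft; code = 2; }
      if (v <= 0.0) { v = 0.0; code = 3; }
      cur[j] = v;
      tb[(size_t)i * (m + 1) + j] = code;
      if (v > best) { best = v; bi = i; bj = j; }
    }
    std::swap(prev, cur);
  }
  std::string ga, gb;
  int i = bi, j = bj;
  while (i > 0 && j > 0) {
    unsigned char code = tb[(size_t)i * (m + 1) + j];
    if (code == 3) break;
    if (code == 0) { ga.push_back(a[--i]); gb.push_back(b[--j]); }
    else if (code == 1) { ga.push_back(a[--i]); gb.push_back('-'); }
    else { ga.push_back('-'); gb.push_back(b[--j]); }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return List::create(_["aligned_a"] = ga, _["aligned_b"] = gb,
                      _["score"] = best,
                      _["a_start"] = i, _["a_end"] = bi,
                      _["b_start"] = j, _["b_end"] = bj);
}
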