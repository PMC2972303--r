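#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// Suffix array by prefix doubling (Manber-Myers, O(n log n)).
// Operates on the raw byte string; sentinels are ordinary characters here
// (callers guarantee they are outside the read alphabet, so no query
// pattern can straddle one).

// [[Rcpp::export]]
IntegerVector sa_build(std::string text) {
  const int n = (int)text.size();
  if (n == 0) return IntegerVector(0);
  std::vector<int> sa(n), rank_(n), tmp(n);
  for (int i = 0; i < n; ++i) {
    sa[i] = i;
    rank_[i] = (unsigned char)text[i];
  }
  for (int len = 1;; len <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rank_[a] != rank_[b]) return rank_[a] < rank_[b];
      int ra = a + len < n ? rank_[a + len] : -1;
      int rb = b + len < n ? rank_[b + len] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rank_ = tmp;
    if (rank_[sa[n - 1]] == n - 1) break;
  }
  // 1-based positions for the R side
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sa[i] + 1;
  return out;
}

// Compare pattern against the suffix starting at pos (0-based).
// Returns <0, 0, >0 as the suffix sorts before / has pattern as prefix /
// sorts after the pattern.
static int suffix_cmp(const std::string& text, int pos, const std::string& pat) {
  const int n = (int)text.size(), m = (int)pat.size();
  for (int j = 0; j < m; ++j) {
    if (pos + j >= n) return -1;  // suffix exhausted: shorter, sorts first
    unsigned char a = (unsigned char)text[pos + j];
    unsigned char b = (unsigned char)pat[j];
    if (a != b) return a < b ? -1 : 1;
  }
  return 0;
}

// [[Rcpp::export]]
int sa_count(std::string text, IntegerVector sa, std::string pattern) {
  const int n = (int)sa.size();
  if (pattern.empty() || n == 0) return 0;
  // lower bound: first suffix with pattern as prefix or sorting after
  int lo = 0, hi = n;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (suffix_cmp(text, sa[mid] - 1, pattern) < 0) lo = mid + 1; else hi = mid;
  }
  int first = lo;
  // upper bound: first suffix sorting strictly after the pattern prefix
  hi = n;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (suffix_cmp(text, sa[mid] - 1, pattern) <= 0) lo = mid + 1; else hi = mid;
  }
  return lo - first;
}

// [[Rcpp::export]]
IntegerVector sa_count_many(std::string text, IntegerVector sa,
                            std::vector<std::string> patterns) {
  const int m = (int)patterns.size();
  IntegerVector out(m);
  for (int i = 0; i < m; ++i) out[i] = sa_count(text, sa, patterns[i]);
  return out;
}
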