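#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// Suffix array by prefix doubling, O(n log^2 n).  Byte order; the record
// sentinel '$' (0x24) sorts before every residue letter, as required for a
// generalized suffix array over sentinel-separated records.
// [[Rcpp::export]]
IntegerVector sa_build(const std::string& text) {
  const int n = (int)text.size();
  if (n <= 1) return IntegerVector(n, 0);
  std::vector<int> sa(n), rnk(n), tmp(n);
  for (int i = 0; i < n; ++i) {
    sa[i] = i;
    rnk[i] = (unsigned char)text[i];
  }
  for (int k = 1;; k <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rnk[a] != rnk[b]) return rnk[a] < rnk[b];
      int ra = a + k < n ? rnk[a + k] : -1;
      int rb = b + k < n ? rnk[b + k] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rnk = tmp;
    if (n == 0 || rnk[sa[n - 1]] == n - 1) break;
  }
  return IntegerVector(sa.begin(), sa.end());  // 0-based positions
}

// Character of suffix sa[i] at depth d, or -1 past the end of the text.
static inline int suf_char(const std::string& text, int pos, int d) {
  size_t p = (size_t)pos + (size_t)d;
  return p < text.size() ? (int)(unsigned char)text[p] : -1;
}

// Narrow the suffix-array interval [lo,hi) of suffixes sharing the first d
// query characters down to those whose character at depth d equals c.
static void narrow(const std::string& text, const IntegerVector& sa, int c,
                   int d, int& lo, int& hi) {
  // lower bound: first i in [lo,hi) with char-at-depth >= c
  int a = lo, b = hi;
  while (a < b) {
    int m = a + (b - a) / 2;
    if (suf_char(text, sa[m], d) < c) a = m + 1; else b = m;
  }
  int nlo = a;
  b = hi;
  while (a < b) {
    int m = a + (b - a) / 2;
    if (suf_char(text, sa[m], d) <= c) a = m + 1; else b = m;
  }
  lo = nlo;
  hi = a;
}

// Longest prefix of query[start..] occurring in text; returns (len, lo, hi)
// with the suffix-array interval of the matched prefix ([0,0) when len = 0).
static void lpm(const std::string& text, const IntegerVector& sa,
                const std::string& query, int start, int& len, int& lo,
                int& hi) {
  int n = sa.size();
  int clo = 0, chi = n, d = 0;
  lo = 0; hi = 0; len = 0;
  int q = (int)query.size();
  while (start + d < q) {
    int c = (int)(unsigned char)query[start + d];
    int nlo = clo, nhi = chi;
    narrow(text, sa, c, d, nlo, nhi);
    if (nlo >= nhi) break;
    clo = nlo; chi = nhi; ++d;
  }
  if (d > 0) { len = d; lo = clo; hi = chi; }
}

// [[Rcpp::export]]
List sa_longest_prefix(const std::string& text, const IntegerVector& sa,
                       const std::string& query, int start) {
  if (start < 0 || start >= (int)query.size())
    stop("start out of range");
  int len, lo, hi;
  lpm(text, sa, query, start, len, lo, hi);
  return List::create(_["length"] = len, _["lo"] = lo, _["hi"] = hi);
}

// [[Rcpp::export]]
List sa_match_interval(const std::string& text, const IntegerVector& sa,
                       const std::string& pattern) {
  int n = sa.size();
  int m = (int)pattern.size();
  if (m == 0)  // every suffix is prefixed by the empty pattern
    return List::create(_["lo"] = 0, _["hi"] = n, _["pattern_len"] = 0);
  int lo = 0, hi = n;
  for (int d = 0; d < m && lo < hi; ++d)
    narrow(text, sa, (int)(unsigned char)pattern[d], d, lo, hi);
  if (lo >= hi) { lo = 0; hi = 0; }
  return List::create(_["lo"] = lo, _["hi"] = hi, _["pattern_len"] = m);
}

// All MEMs of query vs text with length >= min_len.  One longest-prefix
// match per query start; the hit at start i (length l_i) is reported iff
// l_i >= min_len and l_i >= l_{i-1} (left-maximality: the previous start's
// match does not already cover an extension of this one), l_{-1} = 0.
// Columns: start (0-based), len, lo, hi.
// [[Rcpp::export]]
IntegerMatrix sa_find_mems(const std::string& text, const IntegerVector& sa,
                           const std::string& query, int min_len) {
  if (min_len < 1) stop("min_len must be >= 1");
  int q = (int)query.size();
  std::vector<int> st, ln, lov, hiv;
  int prev = 0;
  for (int i = 0; i < q; ++i) {
    int len, lo, hi;
    lpm(text, sa, query, i, len, lo, hi);
    if (len >= min_len && len >= prev) {
      st.push_back(i); ln.push_back(len); lov.push_back(lo); hiv.push_back(hi);
    }
    prev = len;
  }
  IntegerMatrix out((int)st.size(), 4);
  for (int i = 0; i < (int)st.size(); ++i) {
    out(i, 0) = st[i]; out(i, 1) = ln[i]; out(i, 2) = lov[i]; out(i, 3) = hiv[i];
  }
  colnames(out) = CharacterVector::create("start", "len", "lo", "hi");
  return out;
}

// Pairwise tree LCA by parent-pointer climbing with depth equalization.
// parent is 1-based with 0 for the root's parent; nodes are 1-based ids.
static inline int tree_lca(int a, int b, const IntegerVector& parent,
                           const IntegerVector& depth) {
  while (depth[a - 1] > depth[b - 1]) a = parent[a - 1];
  while (depth[b - 1] > depth[a - 1]) b = parent[b - 1];
  while (a != b) { a = parent[a - 1]; b = parent[b - 1]; }
  return a;
}

// Sparse table over the suffix-ordered label array with LCA as the
// idempotent combining operator: st(k, i) = LCA of labels[i .. i + 2^k).
// O(n log n) build; queries combine two overlapping power-of-two blocks.
// [[Rcpp::export]]
IntegerMatrix lca_sparse_build(const IntegerVector& labels,
                               const IntegerVector& parent,
                               const IntegerVector& depth) {
  int n = labels.size();
  if (n == 0) stop("empty label array");
  int K = 1;
  while ((1 << K) <= n) ++K;
  IntegerMatrix st(K, n);
  for (int i = 0; i < n; ++i) st(0, i) = labels[i];
  for (int k = 1; k < K; ++k) {
    int span = 1 << k, half = 1 << (k - 1);
    for (int i = 0; i + span <= n; ++i)
      st(k, i) = tree_lca(st(k - 1, i), st(k - 1, i + half), parent, depth);
  }
  return st;
}

// Range LCA of labels[lo..hi), 0-based half-open, in O(1): one block pair,
// one pairwise LCA (tree height is a small constant independent of hi - lo).
// [[Rcpp::export]]
int lca_sparse_query(const IntegerMatrix& st, const IntegerVector& parent,
                     const IntegerVector& depth, int lo, int hi) {
  if (lo < 0 || hi > st.ncol() || lo >= hi) stop("empty or invalid interval");
  int len = hi - lo;
  int k = 0;
  while ((1 << (k + 1)) <= len) ++k;  // floor(log2(len)); <= 31 iterations
  return tree_lca(st(k, lo), st(k, hi - (1 << k)), parent, depth);
}

// [[Rcpp::export]]
IntegerVector lca_sparse_query_many(const IntegerMatrix& st,
                                    const IntegerVector& parent,
                                    const IntegerVector& depth,
                                    const IntegerVector& lo,
                                    const IntegerVector& hi) {
  int m = lo.size();
  IntegerVector out(m);
  for (int i = 0; i < m; ++i)
    out[i] = lca_sparse_query(st, parent, depth, lo[i], hi[i]);
  return out;
}
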