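#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <string>

using namespace Rcpp;

// Longest-common-subsequence length between two strings. Equals the
// optimal global alignment score under match = 1, mismatch = 0, gap = 0.
// Bit-parallel row DP (Crochemore-Iliopoulos-Pinzon-Reid): the DP row is
// a bit vector updated with word-wide add/subtract, O(nm/64).
// [[Rcpp::export(name = ".lcs_length_cpp")]]
int lcs_length_cpp(const std::string& a, const std::string& b) {
  // bits indexed along the longer string for fewer outer iterations? No:
  // words along `a`, iterate over `b`; choose the shorter for the bit row.
  const std::string& s = (a.size() <= b.size()) ? a : b; // bit row
  const std::string& t = (a.size() <= b.size()) ? b : a; // iterated
  const int n = (int)s.size(), m = (int)t.size();
  if (n == 0) return 0;
  const int W = (n + 63) / 64;
  std::vector<uint64_t> M(256 * W, 0ULL);
  for (int i = 0; i < n; ++i)
    M[(unsigned char)s[i] * W + (i >> 6)] |= (1ULL << (i & 63));
  std::vector<uint64_t> L(W, ~0ULL);
  if (n & 63) L[W - 1] = (1ULL << (n & 63)) - 1ULL; // mask top bits
  std::vector<uint64_t> x(W), sum(W), dif(W);
  for (int j = 0; j < m; ++j) {
    const uint64_t* Mc = &M[(unsigned char)t[j] * W];
    unsigned char carry = 0, borrow = 0;
    for (int w = 0; w < W; ++w) {
      uint64_t xv = L[w] & Mc[w];
      unsigned __int128 sv =
        (unsigned __int128)L[w] + xv + carry;
      carry = (unsigned char)(sv >> 64);
      unsigned __int128 need = (unsigned __int128)xv + borrow;
      uint64_t dv = (uint64_t)((unsigned __int128)L[w] - need);
      borrow = ((unsigned __int128)L[w] < need) ? 1 : 0;
      sum[w] = (uint64_t)sv; dif[w] = dv; x[w] = xv;
    }
    for (int w = 0; w < W; ++w) L[w] = sum[w] | dif[w];
    if (n & 63) L[W - 1] &= (1ULL << (n & 63)) - 1ULL;
  }
  int zeros = 0;
  for (int w = 0; w < W; ++w) {
    uint64_t v = L[w];
    if (w == W - 1 && (n & 63)) v |= ~((1ULL << (n & 63)) - 1ULL);
    zeros += 64 - __builtin_popcountll(v);
  }
  return zeros;
}

// Reference two-row dynamic program, kept as an internal cross-check for
// the bit-parallel routine.
// [[Rcpp::export(name = ".lcs_length_dp_cpp")]]
int lcs_length_dp_cpp(const std::string& a, const std::string& b) {
  const int n = (int)a.size(), m = (int)b.size();
  if (m == 0 || n == 0) return 0;
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    const char si = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      cur[j] = (si == b[j - 1]) ? prev[j - 1] + 1
                                : std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Centred sliding mean with edge clipping: window [i-h, i+h] intersected
// with the array, divided by the number of cells actually used.
// [[Rcpp::export(name = ".rolling_mean_clipped_cpp")]]
NumericVector rolling_mean_clipped_cpp(NumericVector x, int half_width) {
  const int n = x.size();
  NumericVector out(n);
  std::vector<double> cs(n + 1, 0.0);
  for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + x[i];
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - half_width);
    int hi = std::min(n - 1, i + half_width);
    out[i] = (cs[hi + 1] - cs[lo]) / (double)(hi - lo + 1);
  }
  return out;
}

// Type-7 quantile of a sorted buffer (R's default definition).
static double quantile7(std::vector<double>& w, double q) {
  std::sort(w.begin(), w.end());
  const int n = (int)w.size();
  if (n == 1) return w[0];
  double h = (n - 1) * q;
  int lo = (int)std::floor(h);
  int hi = lo + 1 < n ? lo + 1 : lo;
  return w[lo] + (h - lo) * (w[hi] - w[lo]);
}

// Centred rolling type-7 quantile with edge clipping.
// [[Rcpp::export(name = ".rolling_quantile_clipped_cpp")]]
NumericVector rolling_quantile_clipped_cpp(NumericVector x, int half_width,
                                           double q) {
  const int n = x.size();
  NumericVector out(n);
  std::vector<double> w;
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - half_width);
    int hi = std::min(n - 1, i + half_width);
    w.assign(x.begin() + lo, x.begin() + hi + 1);
    out[i] = quantile7(w, q);
  }
  return out;
}
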