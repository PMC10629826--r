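#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>

// Standard dynamic-programming Levenshtein (edit) distance over two byte
// strings. Unit costs for substitution, insertion, deletion.
static int lv_full(const std::string &a, const std::string &b) {
  const int n = a.size(), m = b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Bounded variant: returns the exact distance when it is <= cap, otherwise
// cap + 1. Abandons a row as soon as its minimum exceeds cap.
static int lv_capped(const std::string &a, const std::string &b, int cap) {
  const int n = a.size(), m = b.size();
  if (std::abs(n - m) > cap) return cap + 1;
  if (n == 0) return m;
  if (m == 0) return n;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    int rowmin = cur[0];
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
      rowmin = std::min(rowmin, cur[j]);
    }
    if (rowmin > cap) return cap + 1;
    std::swap(prev, cur);
  }
  return std::min(prev[m], cap + 1);
}

// [[Rcpp::export]]
Rcpp::IntegerVector lv_pairs_cpp(Rcpp::CharacterVector a,
                                 Rcpp::CharacterVector b) {
  R_xlen_t n = a.size();
  if (b.size() != n) Rcpp::stop("a and b must have equal length");
  Rcpp::IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = lv_full(Rcpp::as<std::string>(a[i]), Rcpp::as<std::string>(b[i]));
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::IntegerVector lv_pairs_capped_cpp(Rcpp::CharacterVector a,
                                        Rcpp::CharacterVector b, int cap) {
  R_xlen_t n = a.size();
  if (b.size() != n) Rcpp::stop("a and b must have equal length");
  Rcpp::IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = lv_capped(Rcpp::as<std::string>(a[i]),
                       Rcpp::as<std::string>(b[i]), cap);
  }
  return out;
}

// Cross matrix of bounded distances; entry [i, j] = d(a_i, b_j) exactly when
// <= cap, else cap + 1.
// [[Rcpp::export]]
Rcpp::IntegerMatrix lv_cross_capped_cpp(Rcpp::CharacterVector a,
                                        Rcpp::CharacterVector b, int cap) {
  R_xlen_t n = a.size(), m = b.size();
  std::vector<std::string> as(n), bs(m);
  for (R_xlen_t i = 0; i < n; ++i) as[i] = Rcpp::as<std::string>(a[i]);
  for (R_xlen_t j = 0; j < m; ++j) bs[j] = Rcpp::as<std::string>(b[j]);
  Rcpp::IntegerMatrix out(n, m);
  for (R_xlen_t i = 0; i < n; ++i)
    for (R_xlen_t j = 0; j < m; ++j)
      out(i, j) = lv_capped(as[i], bs[j], cap);
  return out;
}
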