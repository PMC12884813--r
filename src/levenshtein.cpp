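#include <Rcpp.h>
using namespace Rcpp;

// Classic two-row dynamic-programming Levenshtein distance.
static int lev_one(const char *a, int na, const char *b, int nb) {
  if (na == 0) return nb;
  if (nb == 0) return na;
  std::vector<int> prev(nb + 1), cur(nb + 1);
  for (int j = 0; j <= nb; ++j) prev[j] = j;
  for (int i = 1; i <= na; ++i) {
    cur[0] = i;
    for (int j = 1; j <= nb; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[nb];
}

// [[Rcpp::export]]
IntegerVector cpp_levenshtein(CharacterVector s, CharacterVector t) {
  R_xlen_t n = std::max(s.size(), t.size());
  if (s.size() != n && s.size() != 1) stop("s and t lengths are incompatible");
  if (t.size() != n && t.size() != 1) stop("s and t lengths are incompatible");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    String si = s[s.size() == 1 ? 0 : i];
    String ti = t[t.size() == 1 ? 0 : i];
    if (si == NA_STRING || ti == NA_STRING) { out[i] = NA_INTEGER; continue; }
    const char *a = si.get_cstring();
    const char *b = ti.get_cstring();
    out[i] = lev_one(a, (int) strlen(a), b, (int) strlen(b));
  }
  return out;
}

// All-pairs distance matrix for one chain group; symmetric, zero diagonal.
// [[Rcpp::export]]
IntegerMatrix cpp_levenshtein_matrix(CharacterVector s) {
  int n = s.size();
  IntegerMatrix out(n, n);
  std::vector<std::string> v(n);
  for (int i = 0; i < n; ++i) v[i] = as<std::string>(s[i]);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int d = lev_one(v[i].c_str(), (int) v[i].size(), v[j].c_str(), (int) v[j].size());
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}
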