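#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// Decode UTF-8 bytes into codepoints so that distances count characters,
// not bytes (German catalog names carry umlauts and sharp s).
static std::vector<uint32_t> decode_utf8(const char* s) {
  std::vector<uint32_t> out;
  const unsigned char* p = reinterpret_cast<const unsigned char*>(s);
  while (*p) {
    uint32_t cp;
    int extra;
    if (*p < 0x80) {
      cp = *p;
      extra = 0;
    } else if ((*p >> 5) == 0x6) {
      cp = *p & 0x1F;
      extra = 1;
    } else if ((*p >> 4) == 0xE) {
      cp = *p & 0x0F;
      extra = 2;
    } else if ((*p >> 3) == 0x1E) {
      cp = *p & 0x07;
      extra = 3;
    } else {  // invalid lead byte: keep as-is, one unit
      cp = *p;
      extra = 0;
    }
    ++p;
    for (int i = 0; i < extra && (*p >> 6) == 0x2; ++i, ++p) {
      cp = (cp << 6) | (*p & 0x3F);
    }
    out.push_back(cp);
  }
  return out;
}

static int lcs_len(const std::vector<uint32_t>& a, const std::vector<uint32_t>& b) {
  const int m = static_cast<int>(a.size());
  const int n = static_cast<int>(b.size());
  if (m == 0 || n == 0) return 0;
  std::vector<int> prev(n + 1, 0), cur(n + 1, 0);
  for (int i = 1; i <= m; ++i) {
    const uint32_t ai = a[i - 1];
    for (int j = 1; j <= n; ++j) {
      cur[j] = (ai == b[j - 1]) ? prev[j - 1] + 1
                                : std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

static int indel(const std::vector<uint32_t>& a, const std::vector<uint32_t>& b) {
  return static_cast<int>(a.size() + b.size()) - 2 * lcs_len(a, b);
}

// Normalised indel similarity on 0..100, rounded half away from zero.
// Both inputs empty -> 100 (identical); formula yields 0 when exactly one
// side is empty.
static int ratio_pct(const std::vector<uint32_t>& a, const std::vector<uint32_t>& b) {
  const double tot = static_cast<double>(a.size() + b.size());
  if (tot == 0) return 100;
  const double r = 100.0 * (tot - indel(a, b)) / tot;
  return static_cast<int>(std::floor(r + 0.5));
}

static std::vector<uint32_t> decode_elt(const CharacterVector& x, R_xlen_t i) {
  return decode_utf8(Rf_translateCharUTF8(STRING_ELT(x, i)));
}

// [[Rcpp::export(name = ".indel_cpp")]]
IntegerVector indel_cpp(CharacterVector a, CharacterVector b) {
  const R_xlen_t n = std::max(a.size(), b.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(a[i % a.size()]) ||
        CharacterVector::is_na(b[i % b.size()])) {
      out[i] = NA_INTEGER;
      continue;
    }
    out[i] = indel(decode_elt(a, i % a.size()), decode_elt(b, i % b.size()));
  }
  return out;
}

// [[Rcpp::export(name = ".indel_cross_cpp")]]
IntegerMatrix indel_cross_cpp(CharacterVector a, CharacterVector b) {
  const R_xlen_t m = a.size(), n = b.size();
  std::vector<std::vector<uint32_t> > bd(n);
  for (R_xlen_t j = 0; j < n; ++j) bd[j] = decode_elt(b, j);
  IntegerMatrix out(m, n);
  for (R_xlen_t i = 0; i < m; ++i) {
    std::vector<uint32_t> ad = decode_elt(a, i);
    for (R_xlen_t j = 0; j < n; ++j) out(i, j) = indel(ad, bd[j]);
  }
  return out;
}

// [[Rcpp::export(name = ".ratio_cpp")]]
IntegerVector ratio_cpp(CharacterVector a, CharacterVector b) {
  const R_xlen_t n = std::max(a.size(), b.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(a[i % a.size()]) ||
        CharacterVector::is_na(b[i % b.size()])) {
      out[i] = NA_INTEGER;
      continue;
    }
    out[i] = ratio_pct(decode_elt(a, i % a.size()), decode_elt(b, i % b.size()));
  }
  return out;
}

typedef std::vector<std::string> strvec;

static strvec sorted_unique(const CharacterVector& toks) {
  strvec v;
  v.reserve(toks.size());
  for (R_xlen_t i = 0; i < toks.size(); ++i) {
    if (!CharacterVector::is_na(toks[i])) {
      std::string s = Rf_translateCharUTF8(STRING_ELT(toks, i));
      if (!s.empty()) v.push_back(s);
    }
  }
  std::sort(v.begin(), v.end());
  v.erase(std::unique(v.begin(), v.end()), v.end());
  return v;
}

static std::string join(const strvec& v) {
  std::string out;
  for (size_t i = 0; i < v.size(); ++i) {
    if (i) out += ' ';
    out += v[i];
  }
  return out;
}

// Token-set ratio of two token vectors (already normalised): split into
// sorted intersection t0 and remainders; score the three constructions
// t0 vs t0+rest(a), t0 vs t0+rest(b), t0+rest(a) vs t0+rest(b); keep the max.
static int token_set_score(const strvec& ta, const strvec& tb) {
  strvec inter, ra, rb;
  std::set_intersection(ta.begin(), ta.end(), tb.begin(), tb.end(),
                        std::back_inserter(inter));
  std::set_difference(ta.begin(), ta.end(), tb.begin(), tb.end(),
                      std::back_inserter(ra));
  std::set_difference(tb.begin(), tb.end(), ta.begin(), ta.end(),
                      std::back_inserter(rb));
  std::string t0 = join(inter);
  std::string t1 = t0, t2 = t0;
  if (!ra.empty()) t1 = t0.empty() ? join(ra) : t0 + " " + join(ra);
  if (!rb.empty()) t2 = t0.empty() ? join(rb) : t0 + " " + join(rb);
  std::vector<uint32_t> d0 = decode_utf8(t0.c_str());
  std::vector<uint32_t> d1 = decode_utf8(t1.c_str());
  std::vector<uint32_t> d2 = decode_utf8(t2.c_str());
  int best = ratio_pct(d0, d1);
  best = std::max(best, ratio_pct(d0, d2));
  best = std::max(best, ratio_pct(d1, d2));
  return std::min(best, 100);
}

// [[Rcpp::export(name = ".token_set_scores_cpp")]]
IntegerVector token_set_scores_cpp(CharacterVector query_tokens, List choices_tokens) {
  strvec q = sorted_unique(query_tokens);
  const R_xlen_t n = choices_tokens.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    strvec c = sorted_unique(as<CharacterVector>(choices_tokens[i]));
    out[i] = token_set_score(q, c);
  }
  return out;
}

// [[Rcpp::export(name = ".token_set_pair_cpp")]]
int token_set_pair_cpp(CharacterVector a_tokens, CharacterVector b_tokens) {
  return token_set_score(sorted_unique(a_tokens), sorted_unique(b_tokens));
}
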