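#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

// 2-bit DNA codes: A=0, C=1, G=2, T=3; anything else invalid.
// A canonical k-mer (k <= 26) fits in 52 bits, hence is exactly
// representable as an R double on the way out.

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Rolling scan of one sequence; calls f(pos, canonical_code) for every
// valid k-mer start position.
template <typename F>
static void scan_canonical(const char* s, R_xlen_t n, int k, F f) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    int b = base_code(s[i]);
    if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
    if (++run >= k) f(i - k + 1, fwd < rev ? fwd : rev);
  }
}

// [[Rcpp::export]]
DataFrame cpp_count_kmers(CharacterVector seqs, int k) {
  if (k < 1 || k > 26) stop("k must be in [1, 26]");
  std::unordered_map<uint64_t, int> counts;
  counts.reserve(1 << 20);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    scan_canonical(s, (R_xlen_t)LENGTH(STRING_ELT(seqs, i)), k,
                   [&](R_xlen_t, uint64_t code) { ++counts[code]; });
  }
  R_xlen_t m = (R_xlen_t)counts.size();
  NumericVector code(m);
  IntegerVector count(m);
  R_xlen_t j = 0;
  for (const auto& kv : counts) {
    code[j] = (double)kv.first;
    count[j] = kv.second;
    ++j;
  }
  return DataFrame::create(_["code"] = code, _["count"] = count);
}

// [[Rcpp::export]]
DataFrame cpp_locate_kmers(CharacterVector seqs, int k, NumericVector codes) {
  if (k < 1 || k > 26) stop("k must be in [1, 26]");
  std::unordered_set<uint64_t> want;
  want.reserve(codes.size() * 2 + 1);
  for (R_xlen_t i = 0; i < codes.size(); ++i) want.insert((uint64_t)codes[i]);
  std::vector<int> seq_idx;
  std::vector<double> pos;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    scan_canonical(s, (R_xlen_t)LENGTH(STRING_ELT(seqs, i)), k,
                   [&](R_xlen_t p, uint64_t code) {
                     if (want.count(code)) {
                       seq_idx.push_back((int)(i + 1));
                       pos.push_back((double)p);
                     }
                   });
  }
  return DataFrame::create(_["seq_idx"] = wrap(seq_idx), _["start"] = wrap(pos));
}

// [[Rcpp::export]]
CharacterVector cpp_decode_kmers(NumericVector codes, int k) {
  static const char* bases = "ACGT";
  CharacterVector out(codes.size());
  std::string buf(k, 'A');
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    uint64_t c = (uint64_t)codes[i];
    for (int j = k - 1; j >= 0; --j) { buf[j] = bases[c & 3]; c >>= 2; }
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_encode_kmers(CharacterVector kmers, int k) {
  NumericVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    if ((int)LENGTH(STRING_ELT(kmers, i)) != k) stop("k-mer length mismatch");
    uint64_t code = 0;
    for (int j = 0; j < k; ++j) {
      int b = base_code(s[j]);
      if (b < 0) stop("non-ACGT base in k-mer");
      code = (code << 2) | (uint64_t)b;
    }
    out[i] = (double)code;
  }
  return out;
}
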