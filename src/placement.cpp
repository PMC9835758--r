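#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Exact read placer with a sorted seed-k-mer index and a seed-anchored
// mismatch-tolerant fallback. Matching is case-insensitive so soft-masked
// (lowercase) assembly bases participate; repeat handling is delegated to
// the uniqueness policy downstream.

static inline int base2(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char comp(char c) {
  switch (c) {
  case 'A': case 'a': return 'T';
  case 'C': case 'c': return 'G';
  case 'G': case 'g': return 'C';
  case 'T': case 't': return 'A';
  default: return 'N';
  }
}

struct SeedEntry {
  uint64_t code;
  uint32_t scaf;
  uint32_t pos;
};

static bool seed_lt(const SeedEntry& a, const SeedEntry& b) {
  return a.code < b.code;
}

// Encode seed at s[p..p+slen); returns false if any non-ACGT base.
static inline bool seed_code(const char* s, int p, int slen, uint64_t* out) {
  uint64_t code = 0;
  for (int j = 0; j < slen; ++j) {
    int b = base2(s[p + j]);
    if (b < 0) return false;
    code = (code << 2) | (uint64_t)b;
  }
  *out = code;
  return true;
}

struct Cand {
  uint32_t scaf;
  uint32_t pos;
  uint8_t minus;
  int mm;
};

// [[Rcpp::export]]
List cpp_place_reads(CharacterVector reads, CharacterVector scaffolds,
                     int seed_len, double min_identity, bool choose_random) {
  if (seed_len < 8 || seed_len > 31) stop("seed_len must be in [8, 31]");
  R_xlen_t n_scaf = scaffolds.size();
  if (n_scaf == 0) stop("cannot index an empty assembly");

  // Build the seed index.
  std::vector<SeedEntry> index;
  {
    size_t total = 0;
    for (R_xlen_t s = 0; s < n_scaf; ++s) {
      R_xlen_t L = LENGTH(STRING_ELT(scaffolds, s));
      if (L >= seed_len) total += (size_t)(L - seed_len + 1);
    }
    if (total == 0) stop("cannot index an empty assembly");
    index.reserve(total);
  }
  for (R_xlen_t s = 0; s < n_scaf; ++s) {
    const char* sq = CHAR(STRING_ELT(scaffolds, s));
    R_xlen_t L = LENGTH(STRING_ELT(scaffolds, s));
    uint64_t code;
    for (R_xlen_t p = 0; p + seed_len <= L; ++p) {
      if (seed_code(sq, (int)p, seed_len, &code))
        index.push_back({code, (uint32_t)s, (uint32_t)p});
    }
  }
  std::sort(index.begin(), index.end(), seed_lt);

  std::vector<R_xlen_t> scaf_len(n_scaf);
  for (R_xlen_t s = 0; s < n_scaf; ++s)
    scaf_len[s] = LENGTH(STRING_ELT(scaffolds, s));

  R_xlen_t n = reads.size();
  IntegerVector out_scaf(n), out_start(n), out_strand(n), out_nbest(n),
      out_mm(n);
  RNGScope rng;

  std::string rc;
  std::vector<Cand> cands;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* rd = CHAR(STRING_ELT(reads, i));
    int rl = LENGTH(STRING_ELT(reads, i));
    cands.clear();
    if (rl >= seed_len) {
      rc.assign(rl, 'N');
      for (int j = 0; j < rl; ++j) rc[rl - 1 - j] = comp(rd[j]);
      int max_mm = (int)std::floor((1.0 - min_identity) * rl + 1e-9);
      for (int ori = 0; ori < 2; ++ori) {
        const char* q = ori ? rc.c_str() : rd;
        int offs[2] = {0, rl - seed_len};
        int n_off = (offs[1] > 0) ? 2 : 1;
        for (int oi = 0; oi < n_off; ++oi) {
          uint64_t code;
          if (!seed_code(q, offs[oi], seed_len, &code)) continue;
          SeedEntry key{code, 0, 0};
          auto lo = std::lower_bound(index.begin(), index.end(), key, seed_lt);
          for (auto it = lo; it != index.end() && it->code == code; ++it) {
            long a = (long)it->pos - offs[oi];
            if (a < 0 || a + rl > scaf_len[it->scaf]) continue;
            bool dup = false;
            for (const auto& c : cands)
              if (c.scaf == it->scaf && c.pos == (uint32_t)a &&
                  c.minus == (uint8_t)ori) { dup = true; break; }
            if (dup) continue;
            const char* sq = CHAR(STRING_ELT(scaffolds, it->scaf));
            int mm = 0;
            for (int j = 0; j < rl && mm <= max_mm; ++j) {
              int qb = base2(q[j]), sb = base2(sq[a + j]);
              if (qb < 0 || sb < 0 || qb != sb) ++mm;
            }
            if (mm <= max_mm)
              cands.push_back({it->scaf, (uint32_t)a, (uint8_t)ori, mm});
          }
        }
      }
    }
    if (cands.empty()) {
      out_scaf[i] = NA_INTEGER;
      out_start[i] = NA_INTEGER;
      out_strand[i] = NA_INTEGER;
      out_nbest[i] = 0;
      out_mm[i] = NA_INTEGER;
      continue;
    }
    int best = cands[0].mm;
    for (const auto& c : cands) best = std::min(best, c.mm);
    std::vector<int> best_idx;
    for (size_t j = 0; j < cands.size(); ++j)
      if (cands[j].mm == best) best_idx.push_back((int)j);
    int pick = best_idx[0];
    if (choose_random && best_idx.size() > 1)
      pick = best_idx[(int)(unif_rand() * best_idx.size()) % best_idx.size()];
    const Cand& c = cands[pick];
    out_scaf[i] = (int)c.scaf + 1;
    out_start[i] = (int)c.pos;
    out_strand[i] = c.minus ? -1 : 1;
    out_nbest[i] = (int)best_idx.size();
    out_mm[i] = best;
  }
  return List::create(_["scaf_idx"] = out_scaf, _["start"] = out_start,
                      _["strand"] = out_strand, _["n_best"] = out_nbest,
                      _["mismatches"] = out_mm);
}
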