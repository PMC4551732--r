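#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <map>

using namespace Rcpp;

// Histogram of canonical k-mer multiplicities over a set of reads.
// Bases are 2-bit encoded; k-mers containing anything outside ACGT are
// skipped via a rolling validity counter. Canonical = min(fwd, revcomp).
// [[Rcpp::export(name = ".kmer_hist_cpp")]]
DataFrame kmer_hist_cpp(CharacterVector reads, int k) {
  if (k < 3 || k > 31) stop("k must be in [3, 31]");
  if (k % 2 == 0) stop("k must be odd (canonical ambiguity)");

  std::unordered_map<uint64_t, uint32_t> tab;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  const int shift = 2 * (k - 1);

  int code[256];
  for (int i = 0; i < 256; ++i) code[i] = -1;
  code['A'] = 0; code['C'] = 1; code['G'] = 2; code['T'] = 3;
  code['a'] = 0; code['c'] = 1; code['g'] = 2; code['t'] = 3;

  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char *s = CHAR(STRING_ELT(reads, r));
    uint64_t fwd = 0, rev = 0;
    int valid = 0;
    for (const char *p = s; *p; ++p) {
      int c = code[(unsigned char)*p];
      if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
      if (++valid >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        ++tab[canon];
      }
    }
  }

  std::map<uint32_t, double> hist;
  for (const auto &kv : tab) hist[kv.second] += 1.0;

  IntegerVector mult(hist.size());
  NumericVector cnt(hist.size());
  R_xlen_t i = 0;
  for (const auto &kv : hist) {
    mult[i] = (int)kv.first;
    cnt[i] = kv.second;
    ++i;
  }
  return DataFrame::create(_["multiplicity"] = mult, _["count"] = cnt);
}
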