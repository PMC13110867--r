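#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Number of set bits in a packed haplotype.
// [[Rcpp::export(name = ".popcount_raw")]]
int popcount_raw(RawVector x) {
  int n = 0;
  for (R_xlen_t i = 0; i < x.size(); ++i)
    n += __builtin_popcount(static_cast<unsigned char>(x[i]));
  return n;
}

// NH universal hash (64-bit) of a (haplotype, interval set) pair.
//
// The message is serialized as 32-bit words: two length words, the packed
// haplotype bytes, then the interval endpoints as raw IEEE-754 doubles.
// NH(M) = sum_i ((m_{2i} + k_{2i}) mod 2^32) * ((m_{2i+1} + k_{2i+1}) mod
// 2^32) mod 2^64 with a random key stream k.  Pairwise collision probability
// is at most 2^-64 for equal-length messages; the length prefix separates
// messages of different lengths.  Returned as two 32-bit halves.
// [[Rcpp::export(name = ".nh_hash64")]]
IntegerVector nh_hash64(RawVector hap, NumericVector intervals, IntegerVector key) {
  const size_t nb = hap.size();
  const size_t nw_hap = (nb + 3) / 4;
  size_t nw = 2 + nw_hap + 2 * intervals.size();
  if (nw % 2) ++nw;
  if (static_cast<size_t>(key.size()) < nw)
    stop("hash key stream too short (%d < %d words)", key.size(), (int)nw);
  std::vector<uint32_t> m(nw, 0u);
  m[0] = static_cast<uint32_t>(nb);
  m[1] = static_cast<uint32_t>(intervals.size());
  if (nb) std::memcpy(&m[2], RAW(hap), nb);
  if (intervals.size())
    std::memcpy(&m[2 + nw_hap], REAL(intervals), intervals.size() * sizeof(double));
  uint64_t acc = 0;
  for (size_t i = 0; i < nw; i += 2) {
    uint32_t a = m[i]     + static_cast<uint32_t>(key[i]);
    uint32_t b = m[i + 1] + static_cast<uint32_t>(key[i + 1]);
    acc += static_cast<uint64_t>(a) * static_cast<uint64_t>(b);
  }
  IntegerVector out(2);
  out[0] = static_cast<int32_t>(static_cast<uint32_t>(acc & 0xffffffffu));
  out[1] = static_cast<int32_t>(static_cast<uint32_t>(acc >> 32));
  return out;
}
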