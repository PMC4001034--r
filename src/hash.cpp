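#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Counter-based uniform deviates for infinite random masks and random value
// sets.  Membership of a pair (i, j) must be a pure function of
// (seed, stream, i, j): any rank, window or iteration order that queries the
// same pair must see the same realization.  A stateful stream RNG cannot give
// that guarantee, so we use a stateless avalanche mix (the splitmix64
// finalizer) over the counters instead.

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

static inline double pair_u01(uint64_t seed, uint64_t stream,
                              uint64_t i, uint64_t j) {
  uint64_t h = splitmix64(splitmix64(splitmix64(
      seed ^ (stream * 0xda942042e4dd58b5ULL)) ^ i) ^ j);
  // 53 high bits, centered in the bin: u lies strictly inside (0, 1)
  return ((h >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

// [[Rcpp::export]]
NumericVector cpp_pair_u01(double seed, double stream,
                           NumericVector i, NumericVector j) {
  R_xlen_t ni = i.size(), nj = j.size();
  R_xlen_t n = std::max(ni, nj);
  if (!(ni == n || ni == 1) || !(nj == n || nj == 1))
    stop("i and j must have equal length (or length 1)");
  uint64_t s = (uint64_t)(int64_t)seed;
  uint64_t st = (uint64_t)(int64_t)stream;
  NumericVector out(n);
  for (R_xlen_t k = 0; k < n; ++k) {
    uint64_t ii = (uint64_t)(int64_t)(ni == 1 ? i[0] : i[k]);
    uint64_t jj = (uint64_t)(int64_t)(nj == 1 ? j[0] : j[k]);
    out[k] = pair_u01(s, st, ii, jj);
  }
  return out;
}

// All source indices i within the closed intervals [lo_k, hi_k] for which the
// Bernoulli(p) realization of pair (i, j) is present.  This is the hot path
// of iterating a random mask row by row.
// [[Rcpp::export]]
IntegerVector cpp_random_row(double seed, double p,
                             IntegerVector lo, IntegerVector hi, double j) {
  if (p <= 0.0) return IntegerVector(0);
  uint64_t s = (uint64_t)(int64_t)seed;
  uint64_t jj = (uint64_t)(int64_t)j;
  std::vector<int> keep;
  for (R_xlen_t k = 0; k < lo.size(); ++k) {
    for (int i = lo[k]; i <= hi[k]; ++i) {
      if (pair_u01(s, 0, (uint64_t)i, jj) < p) keep.push_back(i);
      if (i == INT_MAX) break;  // guard against overflow wrap
    }
  }
  return wrap(keep);
}
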