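// Exact modular arithmetic for the CGR rolling hash.  Residues live
// modulo the Mersenne prime 2^61 - 1, which exceeds the exact integer
// range of an R double, so values cross the R boundary as (hi, lo)
// splits: hi = v >> 31, lo = v & (2^31 - 1), both exactly representable.
#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

static const uint64_t MOD = 2305843009213693951ULL; // 2^61 - 1

static inline uint64_t mulmod(uint64_t a, uint64_t b) {
  return (uint64_t)(((unsigned __int128)a * b) % MOD);
}
static inline uint64_t addmod(uint64_t a, uint64_t b) {
  uint64_t s = a + b;
  if (s >= MOD) s -= MOD;
  return s;
}
static inline uint64_t submod(uint64_t a, uint64_t b) {
  return a >= b ? a - b : a + MOD - b;
}
static uint64_t powmod(uint64_t b, uint64_t e) {
  uint64_t r = 1;
  while (e) {
    if (e & 1) r = mulmod(r, b);
    b = mulmod(b, b);
    e >>= 1;
  }
  return r;
}
static inline uint64_t joinhl(double hi, double lo) {
  return ((uint64_t)hi << 31) | (uint64_t)lo;
}
static inline void splithl(uint64_t v, double* hi, double* lo) {
  *hi = (double)(v >> 31);
  *lo = (double)(v & ((1ULL << 31) - 1));
}

// Window hash per axis: H = sum_t d_t * 3^(t-1) mod 2^61-1, where d_t is
// the base-3 digit (0 or 2) of window position t (t = 1 is the window's
// first symbol).  This is the scaled digit polynomial of the Cantor
// coordinate of the window.
// [[Rcpp::export(name = ".rk_mod_init")]]
NumericVector rk_mod_init(IntegerVector d1, IntegerVector d2) {
  uint64_t h1 = 0, h2 = 0, p = 1;
  int L = d1.size();
  for (int t = 0; t < L; ++t) {
    h1 = addmod(h1, mulmod((uint64_t)d1[t], p));
    h2 = addmod(h2, mulmod((uint64_t)d2[t], p));
    p = mulmod(p, 3);
  }
  NumericVector out(4);
  splithl(h1, &out[0], &out[1]);
  splithl(h2, &out[2], &out[3]);
  return out;
}

// Slide the window one symbol: H' = (H - d_out) / 3 + d_in * 3^(L-1).
// [[Rcpp::export(name = ".rk_mod_roll")]]
NumericVector rk_mod_roll(NumericVector state, int L,
                          IntegerVector dout, IntegerVector din) {
  uint64_t inv3 = powmod(3, MOD - 2);
  uint64_t pL = powmod(3, (uint64_t)(L - 1));
  NumericVector out(4);
  for (int ax = 0; ax < 2; ++ax) {
    uint64_t h = joinhl(state[2 * ax], state[2 * ax + 1]);
    h = submod(h, (uint64_t)dout[ax]);
    h = mulmod(h, inv3);
    h = addmod(h, mulmod((uint64_t)din[ax], pL));
    splithl(h, &out[2 * ax], &out[2 * ax + 1]);
  }
  return out;
}
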