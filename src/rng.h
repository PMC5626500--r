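#ifndef GRANET_RNG_H
#define GRANET_RNG_H

#include <cstdint>
#include <cmath>

// Deterministic, seed-addressable RNG used throughout the builders and the
// engine so that builds and runs are bit-identical for a fixed master seed,
// independent of R's global RNG state.

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(splitmix64(seed)) {}
  uint64_t next_u64() { s = splitmix64(s); return s; }
  double runif() {
    return (next_u64() >> 11) * (1.0 / 9007199254740992.0);
  }
  double rnorm() {
    // Box-Muller; one draw per call (second value discarded for simplicity)
    double u1 = runif(), u2 = runif();
    if (u1 < 1e-300) u1 = 1e-300;
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }
  int rpois(double lambda) {
    // Knuth for small lambda (used for per-step event counts)
    double ell = std::exp(-lambda), p = 1.0;
    int k = 0;
    do { ++k; p *= runif(); } while (p > ell);
    return k - 1;
  }
};

// Counter-based uniform in [0,1) keyed by (seed, a, b, c): used for per-pair
// acceptance decisions so the result is independent of iteration order.
static inline double hash_runif(uint64_t seed, uint64_t a, uint64_t b,
                                uint64_t c) {
  uint64_t h = splitmix64(seed ^ splitmix64(a ^ splitmix64(b ^ (c * 0x9e37ULL))));
  return (h >> 11) * (1.0 / 9007199254740992.0);
}

#endif
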