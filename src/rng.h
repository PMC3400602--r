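#ifndef HOMEOSTAT_RNG_H
#define HOMEOSTAT_RNG_H

#include <cstdint>
#include <cmath>

// Counter-based RNG: every draw is a pure hash of (seed, step, stream, draw).
// Results are therefore independent of cell iteration order and trivially
// reproducible. splitmix64 finalizer provides the mixing.
static inline uint64_t sm64(uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

static inline uint64_t mix_key(uint64_t seed, uint64_t step, uint64_t stream,
                               uint64_t draw) {
  uint64_t h = sm64(seed ^ 0xd1b54a32d192ed03ULL);
  h = sm64(h ^ step * 0x8cb92ba72f3d8dd7ULL);
  h = sm64(h ^ stream * 0xe7037ed1a0b428dbULL);
  h = sm64(h ^ draw * 0xa0761d6478bd642fULL);
  return h;
}

// uniform in (0,1), never exactly 0 or 1
static inline double u01(uint64_t seed, uint64_t step, uint64_t stream,
                         uint64_t draw) {
  uint64_t h = mix_key(seed, step, stream, draw);
  return ((h >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

// pair of independent standard normals (Box-Muller) from draws (2k, 2k+1)
static inline void norm2(uint64_t seed, uint64_t step, uint64_t stream,
                         uint64_t k, double* z1, double* z2) {
  double u1 = u01(seed, step, stream, 2 * k);
  double u2 = u01(seed, step, stream, 2 * k + 1);
  double r = std::sqrt(-2.0 * std::log(u1));
  *z1 = r * std::cos(6.283185307179586 * u2);
  *z2 = r * std::sin(6.283185307179586 * u2);
}

#endif
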