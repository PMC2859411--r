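#pragma once
#include <cstdint>

namespace pmc {

// xoshiro256++ with splitmix64 seeding.  jump() advances the state by 2^128
// steps, so worker substreams obtained by repeated jumps are non-overlapping
// by construction (each substream has 2^128 draws of headroom).
class Xoshiro256 {
public:
  explicit Xoshiro256(uint64_t sd = 0) { seed(sd); }

  void seed(uint64_t sd) {
    uint64_t x = sd;
    for (int i = 0; i < 4; ++i) s_[i] = splitmix64(x);
  }

  uint64_t next() {
    const uint64_t result = rotl(s_[0] + s_[3], 23) + s_[0];
    const uint64_t t = s_[1] << 17;
    s_[2] ^= s_[0];
    s_[3] ^= s_[1];
    s_[1] ^= s_[2];
    s_[0] ^= s_[3];
    s_[2] ^= t;
    s_[3] = rotl(s_[3], 45);
    return result;
  }

  // advance 2^128 steps
  void jump() {
    static const uint64_t J[] = {0x180ec6d33cfd0abaULL, 0xd5a61266f0c9392cULL,
                                 0xa9582618e03fc9aaULL, 0x39abdc4529b1661cULL};
    uint64_t s0 = 0, s1 = 0, s2 = 0, s3 = 0;
    for (int i = 0; i < 4; ++i)
      for (int b = 0; b < 64; ++b) {
        if (J[i] & (uint64_t(1) << b)) {
          s0 ^= s_[0]; s1 ^= s_[1]; s2 ^= s_[2]; s3 ^= s_[3];
        }
        next();
      }
    s_[0] = s0; s_[1] = s1; s_[2] = s2; s_[3] = s3;
  }

  // uniform on [0, 1), 53-bit resolution
  double unif() { return (next() >> 11) * 0x1.0p-53; }

  // uniform on (0, 1): an exact 0 is remapped to the next draw (log() safety)
  double unif_pos() {
    double u = unif();
    while (u <= 0.0) u = unif();
    return u;
  }

private:
  uint64_t s_[4];
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  static uint64_t splitmix64(uint64_t& x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
};

} // namespace pmc
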