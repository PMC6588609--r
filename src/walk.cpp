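// Random-walk Monte Carlo engine for restricted diffusion.
//
// Each particle owns an independent counter-based RNG stream keyed by
// (seed, particle index), so trajectories are bitwise reproducible and do
// not reshuffle when the particle count changes. Barriers are modelled by
// rejection: a step whose endpoint would leave the restriction is discarded
// and the particle stays in place for that step.
//
// Instead of storing per-step phases for every gradient orientation and
// amplitude, the walk accumulates per particle the 3x3 moment matrix
//   M[a,b] = gamma * dt * sum_t g_a(t) r_b(t)
// for each supplied waveform. The phase for any substrate orientation Rot
// and any amplitude scaling s is then phi = s * sum_ab Rot[a,b] M[a,b],
// which makes the 60-orientation, 12-b-value protocol essentially free.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s[4];
  bool has_cached = false;
  double cached = 0.0;

  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t sd) {
    uint64_t x = sd;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  inline double norm() {
    if (has_cached) { has_cached = false; return cached; }
    double u1;
    do { u1 = unif(); } while (u1 <= 0.0);
    const double u2 = unif();
    const double r = std::sqrt(-2.0 * std::log(u1));
    cached = r * std::sin(2.0 * M_PI * u2);
    has_cached = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

enum Geometry { FREE = 0, SPHERE = 1, CYLINDER = 2 };

inline bool inside(int geom, double R2, double x, double y, double z) {
  switch (geom) {
    case SPHERE:   return x * x + y * y + z * z <= R2;
    case CYLINDER: return x * x + y * y <= R2;
    default:       return true;
  }
}

} // namespace

// [[Rcpp::export]]
List mc_walk_cpp(int geometry, double R, double D0, int n_steps,
                 int n_particles, double dt, NumericMatrix G, double gamma,
                 double seed) {
  const int nw = G.ncol() / 3;
  const double R2 = R * R;
  const double sig = std::sqrt(2.0 * D0 * dt);

  NumericMatrix M(n_particles, 9 * nw);
  NumericVector msd(n_steps);
  NumericMatrix r_final(n_particles, 3);
  double max_out = 0.0;

  // flatten gradient for locality: gflat[t*3nw + c]
  std::vector<double> gflat(static_cast<size_t>(n_steps) * 3 * nw);
  for (int t = 0; t < n_steps; ++t)
    for (int c = 0; c < 3 * nw; ++c)
      gflat[static_cast<size_t>(t) * 3 * nw + c] = G(t, c);

  std::vector<double> acc(9 * nw);

  for (int p = 0; p < n_particles; ++p) {
    Rng rng;
    rng.seed(static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL +
             static_cast<uint64_t>(p) + 1ULL);

    double x = 0.0, y = 0.0, z = 0.0;
    if (geometry == SPHERE) {
      do {
        x = R * (2.0 * rng.unif() - 1.0);
        y = R * (2.0 * rng.unif() - 1.0);
        z = R * (2.0 * rng.unif() - 1.0);
      } while (x * x + y * y + z * z > R2);
    } else if (geometry == CYLINDER) {
      do {
        x = R * (2.0 * rng.unif() - 1.0);
        y = R * (2.0 * rng.unif() - 1.0);
      } while (x * x + y * y > R2);
      z = 0.0;
    }
    const double x0 = x, y0 = y, z0 = z;

    std::fill(acc.begin(), acc.end(), 0.0);

    for (int t = 0; t < n_steps; ++t) {
      const double cx = x + sig * rng.norm();
      const double cy = y + sig * rng.norm();
      const double cz = z + sig * rng.norm();
      if (inside(geometry, R2, cx, cy, cz)) {
        x = cx; y = cy; z = cz;
      }
      if (geometry == SPHERE) {
        const double d = std::sqrt(x * x + y * y + z * z) - R;
        if (d > max_out) max_out = d;
      } else if (geometry == CYLINDER) {
        const double d = std::sqrt(x * x + y * y) - R;
        if (d > max_out) max_out = d;
      }
      const double dx = x - x0, dy = y - y0, dz = z - z0;
      msd[t] += dx * dx + dy * dy + dz * dz;

      if (nw == 0) continue;
      const double *gr = gflat.data() + static_cast<size_t>(t) * 3 * nw;
      for (int w = 0; w < nw; ++w) {
        const double gx = gr[3 * w], gy = gr[3 * w + 1], gz = gr[3 * w + 2];
        double *aw = &acc[9 * w];
        aw[0] += gx * x; aw[1] += gy * x; aw[2] += gz * x;
        aw[3] += gx * y; aw[4] += gy * y; aw[5] += gz * y;
        aw[6] += gx * z; aw[7] += gy * z; aw[8] += gz * z;
      }
    }

    const double k = gamma * dt;
    for (int c = 0; c < 9 * nw; ++c) M(p, c) = acc[c] * k;
    r_final(p, 0) = x; r_final(p, 1) = y; r_final(p, 2) = z;

    if ((p & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }

  for (int t = 0; t < n_steps; ++t) msd[t] /= n_particles;

  return List::create(_["M"] = M, _["msd"] = msd, _["r_final"] = r_final,
                      _["max_outside"] = max_out);
}
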