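// Voxel Monte-Carlo photon transport (MCML-style discrete interactions).
// Works in cm on a column-major (nx, ny, nz) grid with cubic voxels.
#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL) {}
  // splitmix64: portable, deterministic across platforms
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }  // [0,1)
};

inline double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-6) return 2.0 * u - 1.0;
  const double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

inline void spin(double* u, double ct, double phi) {
  const double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  const double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(u[2]) > 0.99999) {
    u[0] = st * cp;
    u[1] = st * sp;
    u[2] = ct * (u[2] >= 0 ? 1.0 : -1.0);
  } else {
    const double den = std::sqrt(1.0 - u[2] * u[2]);
    const double ux = st * (u[0] * u[2] * cp - u[1] * sp) / den + u[0] * ct;
    const double uy = st * (u[1] * u[2] * cp + u[0] * sp) / den + u[1] * ct;
    const double uz = -st * cp * den + u[2] * ct;
    u[0] = ux; u[1] = uy; u[2] = uz;
  }
  const double nrm = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  u[0] /= nrm; u[1] /= nrm; u[2] /= nrm;
}

}  // namespace

// Henyey-Greenstein inverse-CDF sampling from explicit uniforms.
// Returns an n x 2 matrix (cos_theta, azimuth).
// [[Rcpp::export]]
NumericMatrix cpp_sample_hg(double g, const NumericMatrix& u) {
  const int n = u.nrow();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = hg_cos(g, u(i, 0));
    out(i, 1) = 2.0 * M_PI * u(i, 1);
  }
  return out;
}

// Photon packets launched as a flat circular beam normal to one grid face.
// beam = (c1_cm, c2_cm, radius_cm); axis in {0,1,2}; sgn = +1 enters at the
// low face travelling +axis, -1 enters at the high face travelling -axis.
// Deposits w*mu_a/mu_t at each interaction; Russian roulette below
// rr_threshold with survival probability rr_survive.
// [[Rcpp::export]]
List cpp_mc(const NumericVector& mu_a, const NumericVector& mu_s, const NumericVector& g,
            IntegerVector dims, double pitch, NumericVector beam, int axis, int sgn,
            int n_photons, double seed, double rr_threshold, double rr_survive) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long nvox = (long)nx * ny * nz;
  const double ext[3] = {nx * pitch, ny * pitch, nz * pitch};
  NumericVector dep(nvox);
  double absorbed = 0, escaped = 0, rr_killed = 0, rr_gained = 0;
  Rng rng((uint64_t)seed);
  const int a1 = (axis + 1) % 3, a2 = (axis + 2) % 3;
  const double eps = 1e-9 * pitch;

  for (int ph = 0; ph < n_photons; ++ph) {
    // entry position: uniform over the beam disk on the entry face
    double pos[3], dir[3] = {0, 0, 0};
    double r, t1, t2;
    do {
      t1 = 2.0 * rng.unif() - 1.0;
      t2 = 2.0 * rng.unif() - 1.0;
      r = t1 * t1 + t2 * t2;
    } while (r > 1.0);
    pos[a1] = beam[0] + beam[2] * t1;
    pos[a2] = beam[1] + beam[2] * t2;
    pos[axis] = (sgn > 0) ? eps : ext[axis] - eps;
    dir[axis] = (double)sgn;
    if (pos[a1] <= 0 || pos[a1] >= ext[a1] || pos[a2] <= 0 || pos[a2] >= ext[a2]) {
      escaped += 1.0;  // beam wider than the grid face
      continue;
    }
    double w = 1.0;
    double s = -std::log(rng.unif() + 1e-300);
    bool alive = true;
    long guard = 0;
    while (alive && ++guard < 100000000L) {
      int ix = (int)std::floor(pos[0] / pitch), iy = (int)std::floor(pos[1] / pitch),
          iz = (int)std::floor(pos[2] / pitch);
      if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) {
        escaped += w;
        break;
      }
      const long v = ix + (long)nx * (iy + (long)ny * iz);
      const double ma = mu_a[v], ms = mu_s[v];
      const double mt = ma + ms;
      // distance to the nearest voxel boundary along dir
      double db = std::numeric_limits<double>::infinity();
      const int iv[3] = {ix, iy, iz};
      for (int k = 0; k < 3; ++k) {
        if (dir[k] > 1e-12) {
          const double d = ((iv[k] + 1) * pitch - pos[k]) / dir[k];
          if (d < db) db = d;
        } else if (dir[k] < -1e-12) {
          const double d = (iv[k] * pitch - pos[k]) / dir[k];
          if (d < db) db = d;
        }
      }
      if (db < 0) db = 0;
      if (db * mt < s) {  // cross into the next voxel
        const double step = db + eps;
        pos[0] += dir[0] * step; pos[1] += dir[1] * step; pos[2] += dir[2] * step;
        s -= db * mt;
      } else {  // interact inside this voxel
        const double step = s / mt;
        pos[0] += dir[0] * step; pos[1] += dir[1] * step; pos[2] += dir[2] * step;
        const double d = w * ma / mt;
        dep[v] += d;
        absorbed += d;
        w *= ms / mt;
        if (w < rr_threshold) {
          if (rng.unif() < rr_survive) {
            rr_gained += w * (1.0 / rr_survive - 1.0);
            w /= rr_survive;
          } else {
            rr_killed += w;
            alive = false;
            break;
          }
        }
        if (w <= 0) { alive = false; break; }
        const double ct = hg_cos(g[v], rng.unif());
        spin(dir, ct, 2.0 * M_PI * rng.unif());
        s = -std::log(rng.unif() + 1e-300);
      }
    }
  }
  return List::create(_["deposition"] = dep, _["launched"] = (double)n_photons,
                      _["absorbed"] = absorbed, _["escaped"] = escaped,
                      _["rr_killed"] = rr_killed, _["rr_gained"] = rr_gained);
}
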