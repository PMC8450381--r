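// Multi-layer Monte Carlo photon transport (hop-drop-spin with Fresnel
// boundaries and Russian roulette), total diffuse reflectance only.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#if defined(__GNUC__) && !defined(__clang__)
#pragma GCC optimize("O3,unroll-loops")
#endif
using namespace Rcpp;

// splitmix64: used to derive independent per-photon streams so the result
// does not depend on execution order or chunking.
static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

struct Xoshiro256 {
  uint64_t s[4];
  explicit Xoshiro256(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0,1]; never 0 so -log(u) is finite
  inline double runif_pos() {
    return ((next() >> 11) + 1.0) * (1.0 / 9007199254740993.0);
  }
  // uniform in [0,1)
  inline double runif() {
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
};

// Fresnel reflectance for unpolarized light, incidence cosine ca1 >= 0.
static double fresnel(double n1, double n2, double ca1, double &ca2) {
  if (n1 == n2) { ca2 = ca1; return 0.0; }
  if (ca1 > 1.0 - 1e-12) {            // normal incidence
    ca2 = 1.0;
    double r = (n2 - n1) / (n2 + n1);
    return r * r;
  }
  double sa1 = std::sqrt(1.0 - ca1 * ca1);
  double sa2 = n1 * sa1 / n2;
  if (sa2 >= 1.0) { ca2 = 0.0; return 1.0; }   // total internal reflection
  ca2 = std::sqrt(1.0 - sa2 * sa2);
  double cap = ca1 * ca2 - sa1 * sa2;  // cos(a1 + a2)
  double cam = ca1 * ca2 + sa1 * sa2;  // cos(a1 - a2)
  double sap = sa1 * ca2 + ca1 * sa2;  // sin(a1 + a2)
  double sam = sa1 * ca2 - ca1 * sa2;  // sin(a1 - a2)
  double r = 0.5 * sam * sam * (cam * cam + cap * cap) /
             (sap * sap * cam * cam);
  return r;
}

struct LayerSet {
  int n_layers;
  std::vector<double> mua, mus, g, n, z0, z1; // per layer (single band)
};

struct Tally {
  double specular = 0, diffuse = 0, trans = 0, absorbed = 0;
  double sum_d = 0, sum_d2 = 0; // per-photon diffuse contribution moments
};

static void run_band(const LayerSet &L, int n_photons, uint64_t band_seed,
                     double w_thresh, double roulette_p, double max_steps,
                     Tally &tal) {
  const double n_ambient = 1.0;
  double rsp = (n_ambient - L.n[0]) / (n_ambient + L.n[0]);
  rsp = rsp * rsp;
  for (int ip = 0; ip < n_photons; ++ip) {
    uint64_t sd = band_seed;
    sd ^= 0x6a09e667f3bcc909ULL + (uint64_t)ip * 0x9e3779b97f4a7c15ULL;
    Xoshiro256 rng(sd);
    tal.specular += rsp;
    double w = 1.0 - rsp;
    double x = 0, y = 0, z = 0, ux = 0, uy = 0, uz = 1;
    int lay = 0;
    double d_contrib = 0;
    double s_left = 0;        // dimensionless step remaining
    double steps = 0;
    bool alive = true;
    while (alive) {
      if (++steps > max_steps) { tal.absorbed += w; break; }
      double mut = L.mua[lay] + L.mus[lay];
      if (s_left <= 0) s_left = -std::log(rng.runif_pos());
      double s = s_left / mut;
      // distance to layer boundary along uz
      double db = 1e30;
      int dir = 0;
      if (uz > 1e-12)      { db = (L.z1[lay] - z) / uz; dir = +1; }
      else if (uz < -1e-12){ db = (L.z0[lay] - z) / uz; dir = -1; }
      if (db < s) {
        // move to boundary, handle refraction/reflection
        x += ux * db; y += uy * db; z += uz * db;
        s_left -= db * mut;
        double ni = L.n[lay];
        double nt = (dir > 0)
          ? (lay == L.n_layers - 1 ? n_ambient : L.n[lay + 1])
          : (lay == 0 ? n_ambient : L.n[lay - 1]);
        double ca1 = std::fabs(uz), ca2;
        double R = fresnel(ni, nt, ca1, ca2);
        if (rng.runif() > R) {
          // transmit
          if (dir < 0 && lay == 0) {
            tal.diffuse += w; d_contrib += w; alive = false;
          } else if (dir > 0 && lay == L.n_layers - 1) {
            tal.trans += w; alive = false;
          } else {
            double ratio = ni / nt;
            ux *= ratio; uy *= ratio;
            uz = (dir > 0) ? ca2 : -ca2;
            lay += dir;
            z = (dir > 0) ? L.z0[lay] : L.z1[lay];
          }
        } else {
          uz = -uz;
          z = (dir > 0) ? L.z1[lay] : L.z0[lay];
        }
        continue;
      }
      // full hop inside layer
      x += ux * s; y += uy * s; z += uz * s;
      s_left = 0;
      // drop
      double dw = w * L.mua[lay] / mut;
      tal.absorbed += dw;
      w -= dw;
      // spin: Henyey-Greenstein
      double g = L.g[lay];
      double ct;
      if (std::fabs(g) < 1e-6) {
        ct = 2.0 * rng.runif() - 1.0;
      } else {
        double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * rng.runif());
        ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
        if (ct > 1) ct = 1; else if (ct < -1) ct = -1;
      }
      double st = std::sqrt(1.0 - ct * ct);
      // uniform azimuth via Marsaglia rejection (avoids sincos)
      double cp, sp;
      for (;;) {
        double a = 2.0 * rng.runif() - 1.0;
        double b = 2.0 * rng.runif() - 1.0;
        double s2 = a * a + b * b;
        if (s2 > 0.0 && s2 < 1.0) {
          double inv = 1.0 / s2;
          cp = (a * a - b * b) * inv;
          sp = 2.0 * a * b * inv;
          break;
        }
      }
      if (std::fabs(uz) > 0.99999) {
        ux = st * cp; uy = st * sp; uz = (uz >= 0) ? ct : -ct;
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        double nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        double nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        double nuz = -den * st * cp + uz * ct;
        ux = nux; uy = nuy; uz = nuz;
      }
      // Russian roulette; the survivor boost is booked as negative
      // absorption so the four channels sum to the launched weight exactly
      if (w < w_thresh && alive) {
        if (rng.runif() < roulette_p) {
          double boost = w * (1.0 / roulette_p - 1.0);
          tal.absorbed -= boost;
          w += boost;
        } else {
          tal.absorbed += w;
          alive = false;
        }
      }
    }
    tal.sum_d += d_contrib;
    tal.sum_d2 += d_contrib * d_contrib;
  }
}

// mua, mus, g: n_layers x n_bands matrices; n, d: per-layer vectors.
// Returns an n_bands x 5 matrix: diffuse, specular, trans, absorbed, se.
// [[Rcpp::export(name = ".mc_run")]]
NumericMatrix mc_run(NumericMatrix mua, NumericMatrix mus, NumericMatrix g,
                     NumericVector n, NumericVector d, int n_photons,
                     double seed, double w_thresh, double roulette_p,
                     double max_steps) {
  int n_layers = mua.nrow(), n_bands = mua.ncol();
  NumericMatrix out(n_bands, 5);
  uint64_t base = (uint64_t)seed;
  for (int b = 0; b < n_bands; ++b) {
    LayerSet L;
    L.n_layers = n_layers;
    double z = 0;
    for (int l = 0; l < n_layers; ++l) {
      L.mua.push_back(mua(l, b));
      L.mus.push_back(mus(l, b));
      L.g.push_back(g(l, b));
      L.n.push_back(n[l]);
      L.z0.push_back(z);
      z += d[l];
      L.z1.push_back(z);
    }
    uint64_t bs = base;
    bs ^= 0x243f6a8885a308d3ULL + (uint64_t)b * 0xc2b2ae3d27d4eb4fULL;
    Tally tal;
    run_band(L, n_photons, bs, w_thresh, roulette_p, max_steps, tal);
    double N = (double)n_photons;
    double mean_d = tal.sum_d / N;
    double var_d = tal.sum_d2 / N - mean_d * mean_d;
    if (var_d < 0) var_d = 0;
    out(b, 0) = tal.diffuse / N;
    out(b, 1) = tal.specular / N;
    out(b, 2) = tal.trans / N;
    out(b, 3) = tal.absorbed / N;
    out(b, 4) = std::sqrt(var_d / N);
  }
  return out;
}
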