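// Voxel Monte Carlo photon transport with Henyey-Greenstein scattering.
//
// Photon packets are launched uniformly over the top face travelling +z
// (collimated normal incidence). Free paths are sampled in optical depth and
// consumed voxel-by-voxel so media crossings are handled exactly; at each
// interaction the fraction mua/mut of the packet weight is absorbed and the
// remainder scattered. Fluence is estimated with a track-length estimator
// (sum of weighted path lengths per voxel); an absorbed-weight tally is
// accumulated alongside for media with mua > 0.
//
// Randomness is counter-based: every photon owns a splitmix64 stream keyed by
// (seed, photon index), so results are independent of execution order and a
// run is reproducible from (seed, n_photons) alone.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>

namespace {

struct SplitMix64 {
  uint64_t state;
  explicit SplitMix64(uint64_t s) : state(s) {}
  uint64_t next_u64() {
    uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  // uniform in [0, 1)
  double next() { return (next_u64() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform in (0, 1]
  double next_open0() { return 1.0 - next(); }
};

inline uint64_t mix_key(uint64_t seed, uint64_t idx) {
  uint64_t z = seed ^ (idx * 0xd2b74407b1ce6e93ULL + 0x632be59bd9b4e019ULL);
  z = (z ^ (z >> 33)) * 0xff51afd7ed558ccdULL;
  z = (z ^ (z >> 33)) * 0xc4ceb9fe1a85ec53ULL;
  return z ^ (z >> 33);
}

inline double sample_hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-12) return 2.0 * u - 1.0;
  const double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double ct = (1.0 + g * g - f * f) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

}  // namespace

// [[Rcpp::export(name = ".mc_transport_cpp")]]
Rcpp::List mc_transport_cpp(Rcpp::IntegerVector labels,
                            Rcpp::IntegerVector dims,
                            double dx,
                            Rcpp::NumericVector mua,   // per label 0..K-1, mm^-1
                            Rcpp::NumericVector mus,   // per label, mm^-1
                            Rcpp::NumericVector g,     // per label
                            double n_photons,
                            double seed,
                            bool periodic,
                            double roulette_threshold,
                            double roulette_survival,
                            bool tally_absorbed) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = static_cast<R_xlen_t>(nx) * ny * nz;
  if (labels.size() != nvox) Rcpp::stop("labels length does not match dims");
  const int nlab = mua.size();
  const double Lx = nx * dx, Ly = ny * dx;

  std::vector<double> mut(nlab);
  for (int k = 0; k < nlab; ++k) {
    if (mua[k] < 0 || mus[k] < 0) Rcpp::stop("negative optical coefficient");
    if (g[k] <= -1 || g[k] >= 1) Rcpp::stop("g must lie in (-1, 1)");
    mut[k] = mua[k] + mus[k];
  }

  Rcpp::NumericVector track(nvox);       // sum of weight * path length (mm)
  Rcpp::NumericVector adep;              // absorbed weight per voxel
  if (tally_absorbed) adep = Rcpp::NumericVector(nvox);
  std::vector<double> absorbed(nlab, 0.0);
  double escaped_top = 0.0, escaped_other = 0.0;
  double roulette_net = 0.0, lost = 0.0;

  const uint64_t seed64 = static_cast<uint64_t>(seed);
  const R_xlen_t N = static_cast<R_xlen_t>(n_photons);
  const long max_steps = 50000000L;

  for (R_xlen_t ip = 0; ip < N; ++ip) {
    if ((ip & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    SplitMix64 rng(mix_key(seed64, static_cast<uint64_t>(ip)));

    double x = rng.next() * Lx, y = rng.next() * Ly, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    int ix = static_cast<int>(x / dx), iy = static_cast<int>(y / dx), iz = 0;
    if (ix >= nx) ix = nx - 1;
    if (iy >= ny) iy = ny - 1;
    double w = 1.0;
    bool alive = true;
    double s = -std::log(rng.next_open0());  // optical depth to next interaction
    long steps = 0;

    while (alive) {
      if (++steps > max_steps) { lost += w; break; }
      const R_xlen_t idx =
          static_cast<R_xlen_t>(iz) * nx * ny + static_cast<R_xlen_t>(iy) * nx + ix;
      const int lab = labels[idx];
      const double mt = mut[lab];

      // distance to the nearest voxel boundary along the direction of flight
      double tx = R_PosInf, ty = R_PosInf, tz = R_PosInf;
      if (ux > 0)      tx = ((ix + 1) * dx - x) / ux;
      else if (ux < 0) tx = (ix * dx - x) / ux;
      if (uy > 0)      ty = ((iy + 1) * dx - y) / uy;
      else if (uy < 0) ty = (iy * dx - y) / uy;
      if (uz > 0)      tz = ((iz + 1) * dx - z) / uz;
      else if (uz < 0) tz = (iz * dx - z) / uz;
      double db = tx < ty ? (tx < tz ? tx : tz) : (ty < tz ? ty : tz);
      if (db < 0) db = 0;

      const double dint = (mt > 0) ? s / mt : R_PosInf;

      if (dint <= db) {
        // interaction inside this voxel
        x += ux * dint; y += uy * dint; z += uz * dint;
        track[idx] += w * dint;
        const double da = w * (mua[lab] / mt);
        absorbed[lab] += da;
        if (tally_absorbed) adep[idx] += da;
        w -= da;
        if (w <= 0) break;

        const double ct = sample_hg_cos(g[lab], rng.next());
        const double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
        const double phi = 2.0 * M_PI * rng.next();
        const double cp = std::cos(phi), sp = std::sin(phi);
        if (std::fabs(uz) > 0.99999) {
          ux = st * cp; uy = st * sp; uz = ct * (uz >= 0 ? 1.0 : -1.0);
        } else {
          const double den = std::sqrt(1.0 - uz * uz);
          const double nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
          const double nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
          const double nuz = -st * cp * den + uz * ct;
          ux = nux; uy = nuy; uz = nuz;
        }
        const double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
        ux /= norm; uy /= norm; uz /= norm;
        s = -std::log(rng.next_open0());

        if (roulette_threshold > 0 && w < roulette_threshold) {
          if (rng.next() < roulette_survival) {
            const double w_new = w / roulette_survival;
            roulette_net -= (w_new - w);  // weight injected by amplification
            w = w_new;
          } else {
            roulette_net += w;            // weight removed by the kill
            break;
          }
        }
      } else {
        // traverse to the voxel face and cross into the neighbour
        x += ux * db; y += uy * db; z += uz * db;
        track[idx] += w * db;
        if (mt > 0) s -= db * mt;

        if (db == tx) {
          if (ux > 0) { ++ix; x = ix * dx; } else { x = ix * dx; --ix; }
        } else if (db == ty) {
          if (uy > 0) { ++iy; y = iy * dx; } else { y = iy * dx; --iy; }
        } else {
          if (uz > 0) { ++iz; z = iz * dx; } else { z = iz * dx; --iz; }
        }

        if (iz < 0) { escaped_top += w; break; }
        if (iz >= nz) { escaped_other += w; break; }
        if (ix < 0 || ix >= nx) {
          if (periodic) {
            if (ix < 0) { ix = nx - 1; x = Lx; } else { ix = 0; x = 0.0; }
          } else { escaped_other += w; break; }
        }
        if (iy < 0 || iy >= ny) {
          if (periodic) {
            if (iy < 0) { iy = ny - 1; y = Ly; } else { iy = 0; y = 0.0; }
          } else { escaped_other += w; break; }
        }
      }
    }
  }

  Rcpp::NumericVector absorbed_out(nlab);
  for (int k = 0; k < nlab; ++k) absorbed_out[k] = absorbed[k] / n_photons;
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("track") = track,
      Rcpp::Named("absorbed_by_label") = absorbed_out,
      Rcpp::Named("escaped_top") = escaped_top / n_photons,
      Rcpp::Named("escaped_other") = escaped_other / n_photons,
      Rcpp::Named("roulette_net") = roulette_net / n_photons,
      Rcpp::Named("lost") = lost / n_photons);
  if (tally_absorbed) out["absorbed_voxel"] = adep;
  return out;
}

// [[Rcpp::export(name = ".hg_cos_cpp")]]
Rcpp::NumericVector hg_cos_cpp(double g, Rcpp::NumericVector u) {
  Rcpp::NumericVector out(u.size());
  for (R_xlen_t i = 0; i < u.size(); ++i) out[i] = sample_hg_cos(g, u[i]);
  return out;
}
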