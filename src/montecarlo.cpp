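// Correlation-transport photon Monte Carlo for layered turbid media.
//
// Standard photon random walk: exponential free paths with the local mu_s,
// Henyey-Greenstein (or two-term HG) deflections, continuous absorption
// weight attenuation, Russian roulette, index-matched internal boundaries,
// detection on exit through the top surface within an annular detector.
// At each scattering event a Bernoulli draw with the layer's dynamic
// fraction decides whether the scatterer is moving; dynamic events
// accumulate squared momentum transfer q^2 = 2 k^2 (1 - cos theta) per
// layer, which is the sufficient statistic for per-path decorrelation under
// the independent-scatterer (cumulant product) assumption.

#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

static const double C_CM_PS = 2.99792458e10 / 1e12; // cm per ps

struct Rng {
  std::mt19937_64 eng;
  std::uniform_real_distribution<double> unif;
  Rng(uint64_t seed) : eng(seed), unif(0.0, 1.0) {}
  double u() { return unif(eng); }
};

// Henyey-Greenstein cosine sampling; g = 0 reduces to isotropic.
static inline double hg_cos(double g, Rng &rng) {
  if (std::fabs(g) < 1e-8) return 2.0 * rng.u() - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * rng.u());
  double c = (1.0 + g * g - f * f) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// phase_kind: 0 = HG, 1 = two-term HG mixture w*HG(g1) + (1-w)*HG(g2)
static inline double sample_cos(int kind, double g, double g1, double g2,
                                double w, Rng &rng) {
  if (kind == 1) return rng.u() < w ? hg_cos(g1, rng) : hg_cos(g2, rng);
  return hg_cos(g, rng);
}

static inline void rotate_dir(double &ux, double &uy, double &uz,
                              double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = ct * (uz > 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    double nz = -st * cp * den + uz * ct;
    double norm = std::sqrt(nx * nx + ny * ny + nz * nz);
    ux = nx / norm; uy = ny / norm; uz = nz / norm;
  }
}

// [[Rcpp::export]]
List mc_simulate_cpp(NumericMatrix layers, NumericMatrix phase_dyn,
                     double lambda0_nm,
                     double rho_cm, double radius_cm, double accept_rad,
                     int n_photons, double seed, double max_tof_ps,
                     double weight_cutoff, double roulette_survival) {
  // layers columns: 0 thickness, 1 mu_a, 2 mu_s, 3 g_static, 4 g_dynamic,
  //                 5 dynamic_fraction, 6 n_r
  // phase_dyn columns (per layer): 0 kind, 1 g1, 2 g2, 3 w
  const int L = layers.nrow();
  std::vector<double> ztop(L), zbot(L);
  {
    double z = 0.0;
    for (int l = 0; l < L; ++l) {
      ztop[l] = z;
      double th = layers(l, 0);
      z = R_finite(th) ? z + th : R_PosInf;
      zbot[l] = z;
    }
  }
  std::vector<double> k2(L); // squared wavenumber per layer, 1/cm^2
  for (int l = 0; l < L; ++l) {
    double k = 2.0 * M_PI * layers(l, 6) / (lambda0_nm * 1e-7);
    k2[l] = k * k;
  }
  const double cos_accept = std::cos(accept_rad);
  const double rlo = std::max(0.0, rho_cm - radius_cm);
  const double rhi = rho_cm + radius_cm;

  Rng rng((uint64_t)seed);

  std::vector<double> out_tof, out_w, out_maxang;
  std::vector<int> out_ndyn;
  std::vector<std::vector<double>> out_q2(L), out_plen(L);

  for (int ip = 0; ip < n_photons; ++ip) {
    double x = 0, y = 0, z = 0, ux = 0, uy = 0, uz = 1;
    int lay = 0;
    double w = 1.0, tof = 0.0, maxang = 0.0;
    int ndyn = 0;
    std::vector<double> q2sum(L, 0.0), plen(L, 0.0);
    bool alive = true, detected = false;

    while (alive) {
      double tau_opt = -std::log(rng.u()); // optical depth to next scatter
      // propagate, possibly across layer boundaries
      while (tau_opt > 0.0 && alive) {
        double mus = layers(lay, 2);
        double s = tau_opt / mus;
        // distance to layer boundary along uz
        double dbound = R_PosInf;
        if (uz > 1e-12) dbound = (zbot[lay] - z) / uz;
        else if (uz < -1e-12) dbound = (ztop[lay] - z) / uz;
        double step = std::min(s, dbound);
        double nr = layers(lay, 6);
        double dt = step * nr / C_CM_PS;
        if (tof + dt > max_tof_ps) { alive = false; break; }
        x += ux * step; y += uy * step; z += uz * step;
        tof += dt;
        plen[lay] += step;
        w *= std::exp(-layers(lay, 1) * step);
        if (s <= dbound) {
          tau_opt = 0.0; // scatter here
        } else {
          tau_opt -= dbound * mus;
          if (uz < 0 && lay == 0) {
            // exit through the top surface
            alive = false;
            double r = std::sqrt(x * x + y * y);
            if (r >= rlo && r <= rhi && (-uz) >= cos_accept) detected = true;
          } else {
            lay += (uz > 0) ? 1 : -1;
          }
        }
      }
      if (!alive) break;
      // scattering event
      bool dynamic = rng.u() < layers(lay, 5);
      double ct;
      if (dynamic) {
        ct = sample_cos((int)phase_dyn(lay, 0), layers(lay, 4),
                        phase_dyn(lay, 1), phase_dyn(lay, 2),
                        phase_dyn(lay, 3), rng);
        q2sum[lay] += 2.0 * k2[lay] * (1.0 - ct);
        double ang = std::acos(ct);
        if (ang > maxang) maxang = ang;
        ++ndyn;
      } else {
        ct = hg_cos(layers(lay, 3), rng);
      }
      rotate_dir(ux, uy, uz, ct, 2.0 * M_PI * rng.u());
      if (w < weight_cutoff) {
        if (rng.u() < roulette_survival) w /= roulette_survival;
        else alive = false;
      }
    }

    if (detected) {
      out_tof.push_back(tof);
      out_w.push_back(w);
      out_maxang.push_back(maxang);
      out_ndyn.push_back(ndyn);
      for (int l = 0; l < L; ++l) {
        out_q2[l].push_back(q2sum[l]);
        out_plen[l].push_back(plen[l]);
      }
    }
    if ((ip & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  const int nd = (int)out_tof.size();
  NumericMatrix q2(nd, L), pl(nd, L);
  for (int l = 0; l < L; ++l)
    for (int i = 0; i < nd; ++i) {
      q2(i, l) = out_q2[l][i];
      pl(i, l) = out_plen[l][i];
    }
  return List::create(
    _["tof_ps"] = NumericVector(out_tof.begin(), out_tof.end()),
    _["weight"] = NumericVector(out_w.begin(), out_w.end()),
    _["n_dynamic"] = IntegerVector(out_ndyn.begin(), out_ndyn.end()),
    _["max_dynamic_angle"] = NumericVector(out_maxang.begin(), out_maxang.end()),
    _["q2_sum"] = q2,
    _["path_length"] = pl);
}
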