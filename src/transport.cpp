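// Absorption-free (white) Monte Carlo photon transport in a homogeneous
// semi-infinite medium (z >= 0, boundary at z = 0). Photons are launched at
// the origin (or uniformly over a source disk) within the in-tissue NA cone,
// free paths are exponential with rate mu_s, deflection angles come from a
// tabulated inverse CDF, and boundary crossings are handled stochastically
// with unpolarized Fresnel transmission (including total internal
// reflection). Exiting photons are recorded with their radial exit distance,
// total in-medium path length and exit direction cosine; absorption is
// applied retrospectively in R via Beer-Lambert weights.
//
// Two estimators are available:
//  * analog: photons exiting within the acceptance cone and radial cap are
//    recorded with unit weight (one record per detected photon);
//  * peel-off (next-event estimation): at every collision close enough to
//    the surface, the probability of scattering directly into the
//    acceptance cone and escaping without another collision is integrated
//    numerically over the cone and recorded as a weighted contribution.
//    Analog exits are then not recorded (they are already counted in
//    expectation). This drastically reduces variance for narrow cones.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

// xoshiro256++ with splitmix64 seeding: fast, reproducible across platforms
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1]; never returns 0 so log() is safe
  inline double unif() {
    return ((next() >> 11) + 1.0) * (1.0 / 9007199254740993.0);
  }
};

inline double fresnel_T(double mu_i, double n1, double n2) {
  if (std::abs(n1 - n2) < 1e-12) return 1.0;
  double sin_i2 = 1.0 - mu_i * mu_i;
  double sin_t2 = (n1 / n2) * (n1 / n2) * sin_i2;
  if (sin_t2 >= 1.0) return 0.0;  // total internal reflection
  double cos_t = std::sqrt(1.0 - sin_t2);
  double rs = (n1 * mu_i - n2 * cos_t) / (n1 * mu_i + n2 * cos_t);
  double rp = (n1 * cos_t - n2 * mu_i) / (n1 * cos_t + n2 * mu_i);
  return 1.0 - 0.5 * (rs * rs + rp * rp);
}

struct RecordBuf {
  std::vector<double> rho, path, mu, w, photon;
  void push(double r, double l, double m, double wt, double ip) {
    rho.push_back(r); path.push_back(l); mu.push_back(m);
    w.push_back(wt); photon.push_back(ip);
  }
};

}  // namespace

// [[Rcpp::export(name = ".fresnel_transmission_cpp")]]
NumericVector fresnel_transmission_cpp(NumericVector cos_i, double n1,
                                       double n2) {
  NumericVector out(cos_i.size());
  for (R_xlen_t i = 0; i < cos_i.size(); ++i)
    out[i] = fresnel_T(cos_i[i], n1, n2);
  return out;
}

// One transport batch. cos_table: cos(theta) at equally spaced quantiles.
// pdf_table: phase-function density per steradian on a uniform cos(gamma)
//   grid over [-1, 1] (used only by the peel-off estimator).
// source_diam = 0: point source at origin, records keep the radial exit
//   distance (single-integral approximation input), accepted if
//   rho <= rho_max.
// source_diam > 0: uniform source disk of that diameter centered at the
//   origin, the same disk acts as the physical detector (direct-geometry
//   reference mode; analog estimator only).
// [[Rcpp::export(name = ".mc_batch_cpp")]]
List mc_batch_cpp(int n_photons, double mu_s, NumericVector cos_table,
                  double sin_launch, double sin_accept, double rho_max,
                  double n_tissue, double n_external, double max_path,
                  double max_depth, double source_diam, bool uniform_theta,
                  double seed, bool peel = false,
                  NumericVector pdf_table = NumericVector(0)) {
  if (n_photons <= 0) stop("n_photons must be positive");
  if (mu_s <= 0) stop("mu_s must be positive");
  if (peel && (pdf_table.size() < 16 || source_diam > 0))
    stop("peel-off estimation needs a pdf table and a point source");
  Rng rng(static_cast<uint64_t>(seed));
  const int ntab = cos_table.size();
  const double* tab = REAL(cos_table);
  const int npdf = pdf_table.size();
  const double* pdf = (npdf > 0) ? REAL(pdf_table) : nullptr;
  const double cos_launch = std::sqrt(1.0 - sin_launch * sin_launch);
  const double theta_launch = std::asin(sin_launch);
  const double src_r = source_diam / 2.0;
  const double inv_mu_s = 1.0 / mu_s;

  // peel-off cone quadrature: 2-point Gauss-Legendre in mu over
  // [cos(alpha_max), 1], 8 uniform azimuth nodes
  const double mu_acc = std::sqrt(1.0 - sin_accept * sin_accept);
  const int NPHI = 8;
  double cphi[NPHI], sphi[NPHI];
  for (int i = 0; i < NPHI; ++i) {
    double phi = 2.0 * M_PI * (i + 0.5) / NPHI;
    cphi[i] = std::cos(phi); sphi[i] = std::sin(phi);
  }
  const double x_gl = 0.5773502691896258;
  double mu_node[2], mu_wt[2];
  {
    double half = (1.0 - mu_acc) / 2.0, mid = (1.0 + mu_acc) / 2.0;
    mu_node[0] = mid - half * x_gl; mu_node[1] = mid + half * x_gl;
    mu_wt[0] = mu_wt[1] = half;  // weight in d(mu)
  }
  // Russian roulette threshold for small peel-off contributions: records
  // below it are kept with probability w/thresh at weight thresh
  // (unbiased; bounds the record count)
  const double rr_thresh = 1e-3 * 2.0 * M_PI * (1.0 - mu_acc);

  RecordBuf rec;
  long killed_path = 0, killed_depth = 0, exited_rejected = 0;

  for (int ip = 0; ip < n_photons; ++ip) {
    double x = 0.0, y = 0.0, z = 0.0;
    if (src_r > 0.0) {
      double r = src_r * std::sqrt(rng.unif());
      double ang = 2.0 * M_PI * rng.unif();
      x = r * std::cos(ang); y = r * std::sin(ang);
    }
    // launch direction within the in-tissue cone, pointing into the medium
    double ct;
    if (uniform_theta) {
      ct = std::cos(theta_launch * rng.unif());
    } else {
      ct = 1.0 - rng.unif() * (1.0 - cos_launch);  // uniform in solid angle
    }
    double st = std::sqrt(1.0 - ct * ct);
    double phi0 = 2.0 * M_PI * rng.unif();
    double ux = st * std::cos(phi0), uy = st * std::sin(phi0), uz = ct;
    double path = 0.0;

    for (;;) {
      double s = -std::log(rng.unif()) * inv_mu_s;
      // boundary interaction during this step (at most one: reflection
      // turns the photon away from the boundary)
      bool gone = false;
      if (uz < 0.0 && z + uz * s < 0.0) {
        double sb = -z / uz;
        x += ux * sb; y += uy * sb; z = 0.0; path += sb; s -= sb;
        double mu_i = -uz;
        double T = fresnel_T(mu_i, n_tissue, n_external);
        if (rng.unif() < T) {
          // photon leaves the medium
          if (!peel) {
            double sin_exit = std::sqrt(1.0 - mu_i * mu_i);
            bool in_cone = sin_exit <= sin_accept;
            double rho = std::sqrt(x * x + y * y);
            bool in_area = (src_r > 0.0) ? (rho <= src_r) : (rho <= rho_max);
            if (in_cone && in_area)
              rec.push(rho, path, mu_i, 1.0, ip + 1.0);
            else
              ++exited_rejected;
          } else {
            ++exited_rejected;  // counted analytically at collisions
          }
          break;
        }
        uz = -uz;  // specular reflection back into the medium
      }
      x += ux * s; y += uy * s; z += uz * s; path += s;
      if (path > max_path) { ++killed_path; break; }
      if (z > max_depth) { ++killed_depth; break; }
      (void)gone;
      // next-event estimation: probability of scattering from this
      // collision straight into the acceptance cone and escaping
      if (peel) {
        double rho_c = std::sqrt(x * x + y * y);
        double tau_c = mu_s * z;  // optical depth straight up
        if (rho_c <= rho_max && tau_c < 12.0) {
          double wsum = 0.0;
          for (int ia = 0; ia < 2; ++ia) {
            double mu_e = mu_node[ia];
            double sin_e = std::sqrt(1.0 - mu_e * mu_e);
            double att = std::exp(-tau_c / mu_e) *
              fresnel_T(mu_e, n_tissue, n_external);
            if (att <= 0.0) continue;
            double psum = 0.0;
            for (int iphim = 0; iphim < NPHI; ++iphim) {
              // exit direction v = (sin_e c, sin_e s, -mu_e)
              double cg = ux * sin_e * cphi[iphim] +
                uy * sin_e * sphi[iphim] - uz * mu_e;
              double fidx = (cg + 1.0) * 0.5 * (npdf - 1);
              int i0 = static_cast<int>(fidx);
              if (i0 < 0) i0 = 0;
              if (i0 >= npdf - 1) i0 = npdf - 2;
              double f = fidx - i0;
              psum += pdf[i0] + f * (pdf[i0 + 1] - pdf[i0]);
            }
            wsum += mu_wt[ia] * att * psum * (2.0 * M_PI / NPHI);
          }
          if (wsum >= rr_thresh) {
            rec.push(rho_c, path + z, 1.0, wsum, ip + 1.0);
          } else if (wsum > 0.0 && rng.unif() < wsum / rr_thresh) {
            rec.push(rho_c, path + z, 1.0, rr_thresh, ip + 1.0);
          }
        }
      }
      // scatter: deflection cos from the tabulated inverse CDF
      double u = rng.unif() * (ntab - 1);
      int i0 = static_cast<int>(u);
      if (i0 >= ntab - 1) i0 = ntab - 2;
      double f = u - i0;
      ct = tab[i0] + f * (tab[i0 + 1] - tab[i0]);
      if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
      st = std::sqrt(1.0 - ct * ct);
      // azimuth via rejection sampling of a point on the unit circle
      double cf, sf;
      for (;;) {
        double v1 = 2.0 * rng.unif() - 1.0;
        double v2 = 2.0 * rng.unif() - 1.0;
        double r2 = v1 * v1 + v2 * v2;
        if (r2 <= 1.0 && r2 > 1e-12) {
          cf = (v1 * v1 - v2 * v2) / r2;
          sf = 2.0 * v1 * v2 / r2;
          break;
        }
      }
      if (std::abs(uz) > 0.99999) {
        ux = st * cf; uy = st * sf; uz = ct * (uz >= 0 ? 1.0 : -1.0);
      } else {
        double inv_den = 1.0 / std::sqrt(1.0 - uz * uz);
        double nx = st * (ux * uz * cf - uy * sf) * inv_den + ux * ct;
        double ny = st * (uy * uz * cf + ux * sf) * inv_den + uy * ct;
        double nz = -st * cf / inv_den + uz * ct;
        ux = nx; uy = ny; uz = nz;
      }
    }
  }

  R_xlen_t nrec = static_cast<R_xlen_t>(rec.rho.size());
  NumericMatrix m(nrec, 5);
  for (R_xlen_t i = 0; i < nrec; ++i) {
    m(i, 0) = rec.rho[i];
    m(i, 1) = rec.path[i];
    m(i, 2) = rec.mu[i];
    m(i, 3) = rec.w[i];
    m(i, 4) = rec.photon[i];
  }
  colnames(m) = CharacterVector::create("rho", "path_mm", "cos_exit",
                                        "weight", "photon");
  return List::create(_["records"] = m,
                      _["n_launched"] = static_cast<double>(n_photons),
                      _["n_killed_path"] = static_cast<double>(killed_path),
                      _["n_killed_depth"] = static_cast<double>(killed_depth),
                      _["n_exit_rejected"] =
                        static_cast<double>(exited_rejected));
}
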