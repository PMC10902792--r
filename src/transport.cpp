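#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Random-walk engine for fluorescence photons in a homogeneous
// semi-infinite slab (z >= 0, surface at z = 0, air above).
//
// Rules: hop length ~ Exp(mu_t); at each interaction the photon is
// absorbed with probability mu_a/mu_t, otherwise deflected by a
// Henyey-Greenstein angle with mean cosine g. A hop crossing z = 0 is
// advanced exactly to the plane; the unpolarized Fresnel/TIR test (tissue
// index -> air, n = 1) decides transmission. Reflected photons continue
// with mirrored direction for the remaining sub-step. Whole photons are
// tracked (no MCML-style weight decay): counts stay integral for the
// detector model.
//
// All randomness comes from R's global RNG stream (unif_rand), so runs
// are reproducible under set.seed().

static inline double hg_cos(double g, double u) {
  if (g == 0.0) return 2.0 * u - 1.0;
  double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

// unpolarized Fresnel reflectance, cos_i = |cos(incidence angle)|
static inline double fresnel_R(double cos_i, double n_in, double n_out) {
  if (n_in == n_out) return 0.0;
  double sin_i2 = 1.0 - cos_i * cos_i;
  double ratio = n_in / n_out;
  double sin_t2 = ratio * ratio * sin_i2;
  if (sin_t2 >= 1.0) return 1.0;  // total internal reflection
  double cos_t = std::sqrt(1.0 - sin_t2);
  double rs = (n_in * cos_i - n_out * cos_t) / (n_in * cos_i + n_out * cos_t);
  double rp = (n_in * cos_t - n_out * cos_i) / (n_in * cos_t + n_out * cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

// spin direction (ux,uy,uz) by polar angle with cosine ct and azimuth phi
static inline void spin(double &ux, double &uy, double &uz,
                        double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = ct * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double denom = std::sqrt(1.0 - uz * uz);
    double nux = st * (ux * uz * cp - uy * sp) / denom + ux * ct;
    double nuy = st * (uy * uz * cp + ux * sp) / denom + uy * ct;
    double nuz = -st * cp * denom + uz * ct;
    ux = nux; uy = nuy; uz = nuz;
  }
  // renormalize to curb drift over many events
  double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= nrm; uy /= nrm; uz /= nrm;
}

// [[Rcpp::export(name = ".cpp_propagate")]]
List cpp_propagate(int n, double x0, double y0, double z0,
                   double n_tissue, double mu_a, double mu_s, double g,
                   bool fresnel, int max_events) {
  NumericVector exit_x(n, NA_REAL), exit_y(n, NA_REAL);
  NumericVector path(n);
  IntegerVector outcome(n), nsc(n);
  const double mu_t = mu_a + mu_s;
  const double p_abs = mu_a / mu_t;
  RNGScope scope;

  for (int i = 0; i < n; ++i) {
    if (z0 <= 0.0) {  // degenerate surface source: escapes immediately
      outcome[i] = 1; exit_x[i] = x0; exit_y[i] = y0;
      path[i] = 0.0; nsc[i] = 0;
      continue;
    }
    double x = x0, y = y0, z = z0;
    // isotropic initial direction
    double uz = 2.0 * unif_rand() - 1.0;
    double phi = 2.0 * M_PI * unif_rand();
    double sr = std::sqrt(std::max(0.0, 1.0 - uz * uz));
    double ux = sr * std::cos(phi), uy = sr * std::sin(phi);
    double plen = 0.0;
    int events = 0, nscat = 0;
    int out = -1;

    while (out < 0) {
      double s = -std::log1p(-unif_rand()) / mu_t;  // hop
      while (uz < 0.0 && z + s * uz < 0.0) {
        // advance to the surface plane, test the boundary
        double d = z / (-uz);
        x += ux * d; y += uy * d; plen += d;
        s -= d; z = 0.0;
        double cos_i = -uz;
        double R = fresnel ? fresnel_R(cos_i, n_tissue, 1.0) : 0.0;
        if (R == 0.0 || unif_rand() >= R) {
          out = 1; exit_x[i] = x; exit_y[i] = y;  // transmitted
          break;
        }
        uz = -uz;  // internally reflected, continue remaining sub-step
      }
      if (out >= 0) break;
      x += ux * s; y += uy * s; z += uz * s; plen += s;
      if (++events > max_events) { out = 2; break; }  // truncated
      if (unif_rand() < p_abs) { out = 0; break; }    // absorbed
      double ct = hg_cos(g, unif_rand());
      spin(ux, uy, uz, ct, 2.0 * M_PI * unif_rand());
      ++nscat;
    }
    outcome[i] = out;
    path[i] = plen;
    nsc[i] = nscat;
  }
  return List::create(_["outcome"] = outcome, _["exit_x"] = exit_x,
                      _["exit_y"] = exit_y, _["path_length"] = path,
                      _["n_scatter"] = nsc);
}
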