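// Photon-packet Monte Carlo transport through a layered slab (hop-drop-spin
// with implicit capture), an optional bone cylinder, Fresnel/Snell boundary
// physics, Henyey-Greenstein scattering and roulette termination.
//
// All lengths in mm, absorption/scattering coefficients in mm^-1. z is
// positive into the tissue; the source enters at the origin along +z and the
// detector is a disc on the surface centred +x from the source.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

// xoshiro256+ seeded through splitmix64: a named generator-based stream
// fully determined by one 64-bit seed, independent of R's RNG state.
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t x) {
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t r = s[0] + s[3];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  // uniform on (0, 1]: valid argument for -log()
  double unif() { return ((next() >> 11) + 1.0) * (1.0 / 9007199254740992.0); }
};

// unpolarised Fresnel reflectance for incidence cosine ci (>0), n1 -> n2
double fresnel(double ci, double n1, double n2) {
  if (n1 == n2) return 0.0;
  if (ci > 1.0) ci = 1.0;
  const double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  const double st = n1 / n2 * si;
  if (st >= 1.0) return 1.0;  // total internal reflection
  const double ct = std::sqrt(1.0 - st * st);
  if (si < 1e-12) {  // normal incidence limit
    const double r = (n2 - n1) / (n2 + n1);
    return r * r;
  }
  const double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  const double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// Henyey-Greenstein deflection cosine
inline double hg_cos(double g, double xi) {
  if (std::fabs(g) < 1e-6) return 2.0 * xi - 1.0;
  const double f = (1.0 - g * g) / (1.0 + g - 2.0 * g * xi);
  double ct = (1.0 + g * g - f * f) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

struct Photon {
  double x, y, z;
  double ux, uy, uz;
  double w;
  int layer;       // 0-based slab index
  bool in_bone;
  bool alive;
};

struct Tallies {
  double specular = 0, detected = 0, diffuse_reflected = 0,
         transmitted = 0, absorbed = 0, lost = 0;
  long detected_count = 0, launched = 0;
};

struct Geometry {
  int n_layers;
  const double *mu_a, *mu_s, *g, *n, *z0, *z1;
  double n_above, n_below;
  bool has_bone;
  double bone_z, bone_r, bone_mu_a, bone_mu_s, bone_g, bone_n;
  double det_d, det_r;   // detector centre offset and radius on the surface
  double r_max;          // lateral escape cutoff
  double w_threshold, p_survive;
};

// fraction of the circle of radius r (centred on the source) covered by the
// detector disc: the azimuthal-symmetry estimator for a surface disc
double arc_fraction(double r, double d, double a) {
  if (r + d <= a) return 1.0;            // exit circle entirely inside disc
  if (std::fabs(r - d) >= a) return 0.0; // no overlap
  if (r < 1e-12) return (d < a) ? 1.0 : 0.0;
  double c = (r * r + d * d - a * a) / (2.0 * r * d);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return std::acos(c) / M_PI;
}

inline void spin(Photon &p, double g, Xoshiro &rng) {
  const double ct = hg_cos(g, rng.unif());
  const double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  // uniform azimuth by rejection on the unit disc (no trig calls)
  double cp, sp;
  for (;;) {
    const double u = 2.0 * rng.unif() - 1.0;
    const double v = 2.0 * rng.unif() - 1.0;
    const double r2 = u * u + v * v;
    if (r2 <= 1.0 && r2 > 1e-300) {
      cp = (u * u - v * v) / r2;
      sp = 2.0 * u * v / r2;
      break;
    }
  }
  double ux = p.ux, uy = p.uy, uz = p.uz;
  if (std::fabs(uz) > 0.99999) {
    p.ux = st * cp;
    p.uy = st * sp;
    p.uz = ct * (uz >= 0 ? 1.0 : -1.0);
  } else {
    const double den = std::sqrt(1.0 - uz * uz);
    p.ux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    p.uy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    p.uz = -den * st * cp + uz * ct;
  }
  // renormalise only when drift becomes visible
  const double nrm2 = p.ux * p.ux + p.uy * p.uy + p.uz * p.uz;
  if (std::fabs(nrm2 - 1.0) > 1e-12) {
    const double inv = 1.0 / std::sqrt(nrm2);
    p.ux *= inv; p.uy *= inv; p.uz *= inv;
  }
}

// distance along the current direction to the bone cylinder surface
// (axis along y at x = 0, depth bone_z), infinity if not hit
double cylinder_distance(const Photon &p, const Geometry &G, bool from_inside) {
  const double ox = p.x, oz = p.z - G.bone_z;
  const double dx = p.ux, dz = p.uz;
  const double A = dx * dx + dz * dz;
  if (A < 1e-30) return R_PosInf;
  const double B = ox * dx + oz * dz;
  const double C = ox * ox + oz * oz - G.bone_r * G.bone_r;
  const double disc = B * B - A * C;
  if (disc <= 0) return R_PosInf;
  const double sq = std::sqrt(disc);
  const double t1 = (-B - sq) / A, t2 = (-B + sq) / A;
  const double eps = 1e-9;
  if (from_inside) return (t2 > eps) ? t2 : R_PosInf;
  if (t1 > eps) return t1;
  if (t2 > eps) return t2;
  return R_PosInf;
}

int layer_at_depth(const Geometry &G, double z) {
  for (int i = 0; i < G.n_layers; ++i)
    if (z >= G.z0[i] && z < G.z1[i]) return i;
  return (z < G.z0[0]) ? 0 : G.n_layers - 1;
}

// Fresnel interaction at an interface with unit normal (nx, ny, nz) pointing
// against the photon (dot(u, normal) < 0 is arranged by the caller passing
// the outward normal of the medium being left). Returns true if transmitted.
bool interact_interface(Photon &p, double nx, double ny, double nz,
                        double n1, double n2, Xoshiro &rng) {
  double dot = p.ux * nx + p.uy * ny + p.uz * nz;  // > 0: leaving along normal
  const double ci = std::fabs(dot);
  const double R = fresnel(ci, n1, n2);
  if (rng.unif() <= R) {
    // specular reflection about the normal
    p.ux -= 2.0 * dot * nx;
    p.uy -= 2.0 * dot * ny;
    p.uz -= 2.0 * dot * nz;
    return false;
  }
  // Snell refraction
  const double eta = n1 / n2;
  const double ct = std::sqrt(std::max(0.0, 1.0 - eta * eta * (1.0 - ci * ci)));
  const double sgn = (dot >= 0) ? 1.0 : -1.0;
  p.ux = eta * p.ux + (ct - eta * ci) * sgn * nx;
  p.uy = eta * p.uy + (ct - eta * ci) * sgn * ny;
  p.uz = eta * p.uz + (ct - eta * ci) * sgn * nz;
  const double nrm = std::sqrt(p.ux * p.ux + p.uy * p.uy + p.uz * p.uz);
  p.ux /= nrm; p.uy /= nrm; p.uz /= nrm;
  return true;
}

void trace_packet(const Geometry &G, Xoshiro &rng, Tallies &T) {
  Photon p;
  p.x = p.y = p.z = 0.0;
  p.ux = p.uy = 0.0; p.uz = 1.0;
  p.layer = 0; p.in_bone = false; p.alive = true;

  // specular loss at the air-tissue surface (normal incidence pencil beam)
  const double rsp = fresnel(1.0, G.n_above, G.n[0]);
  T.specular += rsp;
  p.w = 1.0 - rsp;
  p.z = 1e-9;

  double sleft = 0.0;  // dimensionless step remaining
  const double eps = 1e-9;

  while (p.alive) {
    double mu_a, mu_s, g_aniso, n_med;
    if (p.in_bone) {
      mu_a = G.bone_mu_a; mu_s = G.bone_mu_s; g_aniso = G.bone_g; n_med = G.bone_n;
    } else {
      mu_a = G.mu_a[p.layer]; mu_s = G.mu_s[p.layer];
      g_aniso = G.g[p.layer]; n_med = G.n[p.layer];
    }
    const double mu_t = mu_a + mu_s;

    if (sleft <= 0.0) sleft = -std::log(rng.unif());
    double step = (mu_t > 0.0) ? sleft / mu_t : R_PosInf;

    // nearest boundary along the direction of flight
    double db = R_PosInf;
    int boundary = 0;  // 1: slab above, 2: slab below, 3: cylinder
    if (!p.in_bone) {
      if (p.uz < 0.0) { db = (G.z0[p.layer] - p.z) / p.uz; boundary = 1; }
      else if (p.uz > 0.0) { db = (G.z1[p.layer] - p.z) / p.uz; boundary = 2; }
      if (G.has_bone) {
        const double dc = cylinder_distance(p, G, false);
        if (dc < db) { db = dc; boundary = 3; }
      }
    } else {
      db = cylinder_distance(p, G, true);
      boundary = 3;
    }

    if (db <= step) {
      // hop to the boundary, pay the consumed optical depth
      p.x += db * p.ux; p.y += db * p.uy; p.z += db * p.uz;
      if (mu_t > 0.0) sleft -= db * mu_t;

      if (boundary == 3) {
        // bone cylinder surface: radial normal in the x-z plane
        double nx = p.x - 0.0, nz = p.z - G.bone_z;
        const double nn = std::sqrt(nx * nx + nz * nz);
        nx /= nn; nz /= nn;
        if (!p.in_bone) { nx = -nx; nz = -nz; }  // outward from current medium
        const double n_other = p.in_bone ? G.n[layer_at_depth(G, p.z)] : G.bone_n;
        if (interact_interface(p, nx, 0.0, nz, n_med, n_other, rng)) {
          p.in_bone = !p.in_bone;
          if (!p.in_bone) p.layer = layer_at_depth(G, p.z);
          sleft = 0.0;  // new medium: re-sample the free path
        }
        p.x += eps * p.ux; p.y += eps * p.uy; p.z += eps * p.uz;
      } else {
        const bool upward = (boundary == 1);
        const int next = upward ? p.layer - 1 : p.layer + 1;
        const double n_next = (next < 0) ? G.n_above
                            : (next >= G.n_layers) ? G.n_below
                            : G.n[next];
        // slab plane normal along z, pointing out of the current layer
        const double nz = upward ? -1.0 : 1.0;
        if (interact_interface(p, 0.0, 0.0, nz, n_med, n_next, rng)) {
          if (next < 0) {
            // escaped through the surface
            T.diffuse_reflected += p.w;
            const double r = std::sqrt(p.x * p.x + p.y * p.y);
            const double f = arc_fraction(r, G.det_d, G.det_r);
            if (f > 0.0) { T.detected += p.w * f; T.detected_count++; }
            p.alive = false;
          } else if (next >= G.n_layers) {
            T.transmitted += p.w;
            p.alive = false;
          } else {
            p.layer = next;
            sleft = 0.0;
          }
        }
        p.z += eps * p.uz;  // nudge off the plane
        if (p.z <= 0.0) p.z = eps;
        if (p.z >= G.z1[G.n_layers - 1]) p.z = G.z1[G.n_layers - 1] - eps;
      }
    } else {
      // hop to the interaction site
      p.x += step * p.ux; p.y += step * p.uy; p.z += step * p.uz;
      sleft = 0.0;
      if (p.x * p.x + p.y * p.y > G.r_max * G.r_max) {
        T.absorbed += p.w; T.lost += p.w;
        p.alive = false;
        continue;
      }
      if (mu_t > 0.0) {
        const double dw = p.w * mu_a / mu_t;  // implicit capture
        T.absorbed += dw;
        p.w -= dw;
        spin(p, g_aniso, rng);
      }
      if (p.alive && p.w < G.w_threshold) {
        // roulette; the tally bookkeeping keeps every run exactly
        // energy-conserving while the expectation stays unbiased
        if (rng.unif() <= G.p_survive) {
          const double w_new = p.w / G.p_survive;
          T.absorbed += p.w - w_new;
          p.w = w_new;
        } else {
          T.absorbed += p.w;
          p.alive = false;
        }
      }
    }
  }
}

}  // namespace

//' @noRd
// [[Rcpp::export]]
List mc_transport_cpp(NumericMatrix layers, double n_above, double n_below,
                      double det_offset, double det_radius,
                      std::string stop_mode, double stop_target,
                      double max_launched, double r_max,
                      double w_threshold, double p_survive,
                      Nullable<NumericVector> bone, double seed) {
  const int nl = layers.nrow();
  if (nl < 1) stop("at least one layer required");
  if (stop_target < 1) stop("stop target must be >= 1");
  std::vector<double> mu_a(nl), mu_s(nl), g(nl), n(nl), z0(nl), z1(nl);
  for (int i = 0; i < nl; ++i) {
    mu_a[i] = layers(i, 0); mu_s[i] = layers(i, 1); g[i] = layers(i, 2);
    n[i] = layers(i, 3); z0[i] = layers(i, 4); z1[i] = layers(i, 5);
    if (!R_finite(mu_a[i]) || mu_a[i] < 0 || !R_finite(mu_s[i]) || mu_s[i] < 0)
      stop("layer %d has a non-finite or negative optical property", i + 1);
  }
  Geometry G;
  G.n_layers = nl;
  G.mu_a = mu_a.data(); G.mu_s = mu_s.data(); G.g = g.data(); G.n = n.data();
  G.z0 = z0.data(); G.z1 = z1.data();
  G.n_above = n_above; G.n_below = n_below;
  G.det_d = det_offset; G.det_r = det_radius;
  G.r_max = r_max; G.w_threshold = w_threshold; G.p_survive = p_survive;
  G.has_bone = bone.isNotNull();
  if (G.has_bone) {
    NumericVector b(bone);  // depth, radius, mu_a, mu_s, g, n
    G.bone_z = b[0]; G.bone_r = b[1]; G.bone_mu_a = b[2];
    G.bone_mu_s = b[3]; G.bone_g = b[4]; G.bone_n = b[5];
  }

  const bool by_detected = (stop_mode == "detected");
  if (!by_detected && stop_mode != "launched")
    stop("stop_mode must be 'detected' or 'launched'");

  // Per-packet substreams: packet i always starts from the same generator
  // state for a given seed, whatever the geometry. Runs that differ only in
  // optical properties are therefore common-random-number paired, and a
  // parallel split over packets would reproduce the serial result.
  const uint64_t seed_base = static_cast<uint64_t>(seed);
  Tallies T;
  while (true) {
    if (by_detected) {
      if (T.detected_count >= (long)stop_target) break;
      if (T.launched >= (long)max_launched)
        stop("launched-packet cap reached before the detected target; "
             "the detector may be unreachable in this geometry");
    } else {
      if (T.launched >= (long)stop_target) break;
    }
    Xoshiro rng(seed_base ^ ((uint64_t)(T.launched + 1) * 0x9e3779b97f4a7c15ULL));
    trace_packet(G, rng, T);
    T.launched++;
    if ((T.launched & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  const double launched_weight = (double)T.launched;
  return List::create(
    _["launched_count"] = (double)T.launched,
    _["launched_weight"] = launched_weight,
    _["detected_count"] = (double)T.detected_count,
    _["detected_weight"] = T.detected,
    _["diffuse_reflected_weight"] = T.diffuse_reflected,
    _["transmitted_weight"] = T.transmitted,
    _["absorbed_weight"] = T.absorbed,
    _["lost_weight"] = T.lost,
    _["specular_weight"] = T.specular,
    _["reflectance"] = T.detected / launched_weight,
    _["total_reflectance"] = (T.specular + T.diffuse_reflected) / launched_weight,
    _["transmittance"] = T.transmitted / launched_weight);
}

//' @noRd
// [[Rcpp::export]]
NumericVector mc_uniform_cpp(int n, double seed) {
  Xoshiro rng(static_cast<uint64_t>(seed));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.unif();
  return out;
}

//' @noRd
// [[Rcpp::export]]
NumericVector mc_sample_steps_cpp(int n, double mu_t, double seed) {
  if (mu_t <= 0) stop("mu_t must be > 0");
  Xoshiro rng(static_cast<uint64_t>(seed));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = -std::log(rng.unif()) / mu_t;
  return out;
}

//' @noRd
// [[Rcpp::export]]
NumericVector mc_hg_cos_cpp(int n, double g, double seed) {
  if (g < -1 || g > 1) stop("anisotropy g must lie in [-1, 1]");
  Xoshiro rng(static_cast<uint64_t>(seed));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = hg_cos(g, rng.unif());
  return out;
}

//' @noRd
// [[Rcpp::export]]
NumericMatrix mc_scatter_cpp(NumericVector direction, double g, int n, double seed) {
  if (direction.size() != 3) stop("direction must have length 3");
  Xoshiro rng(static_cast<uint64_t>(seed));
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    Photon p;
    p.ux = direction[0]; p.uy = direction[1]; p.uz = direction[2];
    const double nrm = std::sqrt(p.ux * p.ux + p.uy * p.uy + p.uz * p.uz);
    p.ux /= nrm; p.uy /= nrm; p.uz /= nrm;
    spin(p, g, rng);
    out(i, 0) = p.ux; out(i, 1) = p.uy; out(i, 2) = p.uz;
  }
  return out;
}

//' @noRd
// [[Rcpp::export]]
NumericVector fresnel_reflectance_cpp(NumericVector cos_i, double n1, double n2) {
  NumericVector out(cos_i.size());
  for (int i = 0; i < cos_i.size(); ++i) {
    if (cos_i[i] < 0 || cos_i[i] > 1) stop("cos_i must lie in [0, 1]");
    out[i] = fresnel(cos_i[i], n1, n2);
  }
  return out;
}

//' @noRd
// [[Rcpp::export]]
NumericVector mc_roulette_cpp(NumericVector weights, double threshold,
                              double p_survive, double seed) {
  Xoshiro rng(static_cast<uint64_t>(seed));
  NumericVector out(weights.size());
  for (int i = 0; i < weights.size(); ++i) {
    double w = weights[i];
    if (w < threshold) {
      w = (rng.unif() <= p_survive) ? w / p_survive : 0.0;
    }
    out[i] = w;
  }
  return out;
}

//' @noRd
// [[Rcpp::export]]
NumericVector arc_fraction_cpp(NumericVector r, double d, double a) {
  NumericVector out(r.size());
  for (int i = 0; i < r.size(); ++i) out[i] = arc_fraction(r[i], d, a);
  return out;
}
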