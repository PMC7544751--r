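// Core Monte Carlo kernel: constructive-solid geometry queries and analog
// photon transport with per-region energy-deposition tallies.
//
// All randomness goes through R's RNG (unif_rand), so set.seed() on the R
// side makes every sampler in here reproducible.
//
// Units: cm, MeV, g. Linear attenuation coefficients are passed in 1/cm on
// a log-log grid per material.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double ME_C2 = 0.51099895; // electron rest energy, MeV
static const double NUDGE = 1e-7;       // cm, boundary-crossing push
static const double TINY = 1e-12;

// ---------------------------------------------------------------------------
// Shapes.  kind: 0 = box, 1 = finite cylinder (p3 = inner radius, 0 solid),
// 2 = elliptical tube.  axis: 0/1/2 for x/y/z (box ignores it).  For an
// axial shape the two transverse coordinates are the remaining axes in
// ascending index order.  p1,p2,p3 are half-extents / radii as noted below.
struct Shape {
  int kind, axis;
  double c[3];
  double p1, p2, p3;
  // box:   p1,p2,p3 = half-extent x, y, z
  // cyl:   p1 = outer radius, p2 = half-length, p3 = inner radius (>=0)
  // etube: p1 = semi-axis (first transverse), p2 = semi-axis (second),
  //        p3 = half-length along axis
};

struct Scene {
  std::vector<Shape> shapes;   // priority order: most specific first,
                               // world box last
  std::vector<int> mat;        // material index per region (0-based)
};

static inline void trans_axes(int axis, int &u, int &v) {
  if (axis == 0) { u = 1; v = 2; }
  else if (axis == 1) { u = 0; v = 2; }
  else { u = 0; v = 1; }
}

static bool inside_shape(const Shape &s, const double p[3]) {
  double d0 = p[0] - s.c[0], d1 = p[1] - s.c[1], d2 = p[2] - s.c[2];
  if (s.kind == 0) {
    return std::fabs(d0) <= s.p1 && std::fabs(d1) <= s.p2 &&
           std::fabs(d2) <= s.p3;
  }
  double d[3] = {d0, d1, d2};
  int u, v; trans_axes(s.axis, u, v);
  double da = d[s.axis];
  if (s.kind == 1) {
    if (std::fabs(da) > s.p2) return false;
    double r2 = d[u] * d[u] + d[v] * d[v];
    if (r2 > s.p1 * s.p1) return false;
    if (s.p3 > 0.0 && r2 < s.p3 * s.p3) return false;
    return true;
  }
  // elliptical tube
  if (std::fabs(da) > s.p3) return false;
  double eu = d[u] / s.p1, ev = d[v] / s.p2;
  return eu * eu + ev * ev <= 1.0;
}

// Quadratic helper: collect positive roots of a t^2 + b t + c = 0
static inline void quad_roots(double a, double b, double c,
                              std::vector<double> &out) {
  if (std::fabs(a) < TINY) {
    if (std::fabs(b) > TINY) out.push_back(-c / b);
    return;
  }
  double disc = b * b - 4.0 * a * c;
  if (disc <= 0.0) return;
  double sd = std::sqrt(disc);
  double q = (b > 0.0) ? -0.5 * (b + sd) : -0.5 * (b - sd);
  out.push_back(q / a);
  if (std::fabs(q) > TINY) out.push_back(c / q);
}

// Candidate parameter values where the ray o + t*d crosses a surface patch
// of the shape.  Patch-validity is checked so spurious plane/quadric
// crossings outside the solid's faces are discarded.
static void shape_crossings(const Shape &s, const double o[3],
                            const double d[3], std::vector<double> &ts) {
  double oc[3] = {o[0] - s.c[0], o[1] - s.c[1], o[2] - s.c[2]};
  if (s.kind == 0) {
    double h[3] = {s.p1, s.p2, s.p3};
    for (int i = 0; i < 3; ++i) {
      if (std::fabs(d[i]) < TINY) continue;
      for (int sgn = -1; sgn <= 1; sgn += 2) {
        double t = (sgn * h[i] - oc[i]) / d[i];
        if (t <= 0.0) continue;
        bool ok = true;
        for (int j = 0; j < 3; ++j) {
          if (j == i) continue;
          double pj = oc[j] + t * d[j];
          if (std::fabs(pj) > h[j] + 1e-9) { ok = false; break; }
        }
        if (ok) ts.push_back(t);
      }
    }
    return;
  }
  int u, v; trans_axes(s.axis, u, v);
  int a = s.axis;
  double hl = (s.kind == 1) ? s.p2 : s.p3;
  // lateral surface(s)
  std::vector<double> roots;
  if (s.kind == 1) {
    double A = d[u] * d[u] + d[v] * d[v];
    double B = 2.0 * (oc[u] * d[u] + oc[v] * d[v]);
    double C0 = oc[u] * oc[u] + oc[v] * oc[v];
    quad_roots(A, B, C0 - s.p1 * s.p1, roots);
    if (s.p3 > 0.0) quad_roots(A, B, C0 - s.p3 * s.p3, roots);
  } else {
    double su = d[u] / s.p1, sv = d[v] / s.p2;
    double pu = oc[u] / s.p1, pv = oc[v] / s.p2;
    double A = su * su + sv * sv;
    double B = 2.0 * (pu * su + pv * sv);
    double C0 = pu * pu + pv * pv - 1.0;
    quad_roots(A, B, C0, roots);
  }
  for (double t : roots) {
    if (t <= 0.0) continue;
    double pa = oc[a] + t * d[a];
    if (std::fabs(pa) <= hl + 1e-9) ts.push_back(t);
  }
  // end caps
  if (std::fabs(d[a]) > TINY) {
    for (int sgn = -1; sgn <= 1; sgn += 2) {
      double t = (sgn * hl - oc[a]) / d[a];
      if (t <= 0.0) continue;
      double pu = oc[u] + t * d[u], pv = oc[v] + t * d[v];
      if (s.kind == 1) {
        double r2 = pu * pu + pv * pv;
        if (r2 <= s.p1 * s.p1 + 1e-9 &&
            (s.p3 <= 0.0 || r2 >= s.p3 * s.p3 - 1e-9))
          ts.push_back(t);
      } else {
        double eu = pu / s.p1, ev = pv / s.p2;
        if (eu * eu + ev * ev <= 1.0 + 1e-9) ts.push_back(t);
      }
    }
  }
}

static int locate_point(const Scene &sc, const double p[3]) {
  int n = (int)sc.shapes.size();
  for (int i = 0; i < n; ++i)
    if (inside_shape(sc.shapes[i], p)) return i;
  return -1; // outside world
}

// Distance to the next region change along the ray, and the region entered.
// Returns distance; next region via *next (-1 = outside world).
static double dist_to_boundary(const Scene &sc, const double o[3],
                               const double d[3], int cur, int *next) {
  std::vector<double> ts;
  ts.reserve(64);
  for (const Shape &s : sc.shapes) shape_crossings(s, o, d, ts);
  std::sort(ts.begin(), ts.end());
  double pr[3];
  for (double t : ts) {
    if (t < 1e-9) continue;
    pr[0] = o[0] + (t + NUDGE) * d[0];
    pr[1] = o[1] + (t + NUDGE) * d[1];
    pr[2] = o[2] + (t + NUDGE) * d[2];
    int reg = locate_point(sc, pr);
    if (reg != cur) { *next = reg; return t; }
  }
  *next = -1; // should only happen from numerical edge cases at the world face
  return ts.empty() ? 0.0 : ts.back();
}

static Scene scene_from_matrix(const NumericMatrix &m) {
  Scene sc;
  int n = m.nrow();
  sc.shapes.resize(n);
  sc.mat.resize(n);
  for (int i = 0; i < n; ++i) {
    Shape &s = sc.shapes[i];
    s.kind = (int)m(i, 0);
    s.axis = (int)m(i, 1);
    s.c[0] = m(i, 2); s.c[1] = m(i, 3); s.c[2] = m(i, 4);
    s.p1 = m(i, 5); s.p2 = m(i, 6); s.p3 = m(i, 7);
    sc.mat[i] = (int)m(i, 8) - 1; // R side passes 1-based material indices
  }
  return sc;
}

// ---------------------------------------------------------------------------
// Material tables: per material, log(E) grid and log(mu) per channel (1/cm).
struct MatTab {
  std::vector<double> logE, pe, inc, coh;
};

static std::vector<MatTab> mats_from_list(const List &l) {
  std::vector<MatTab> out;
  for (int i = 0; i < l.size(); ++i) {
    List mi = l[i];
    MatTab t;
    NumericVector le = mi["logE"], pe = mi["log_pe"], in = mi["log_inc"],
                  co = mi["log_coh"];
    t.logE.assign(le.begin(), le.end());
    t.pe.assign(pe.begin(), pe.end());
    t.inc.assign(in.begin(), in.end());
    t.coh.assign(co.begin(), co.end());
    out.push_back(t);
  }
  return out;
}

// log-log interpolation of one channel, clamped to the grid ends
static double interp_mu(const std::vector<double> &logE,
                        const std::vector<double> &logMu, double E) {
  double x = std::log(E);
  int n = (int)logE.size();
  if (x <= logE[0]) return std::exp(logMu[0]);
  if (x >= logE[n - 1]) return std::exp(logMu[n - 1]);
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (logE[mid] <= x) lo = mid; else hi = mid;
  }
  double w = (x - logE[lo]) / (logE[hi] - logE[lo]);
  return std::exp(logMu[lo] + w * (logMu[hi] - logMu[lo]));
}

// ---------------------------------------------------------------------------
// Klein-Nishina sampling of the Compton scattering angle (Kahn's
// composition-rejection method).  k = E / (m_e c^2).  Returns cos(theta).
static double kn_sample_costheta(double k) {
  double r1, r2, r3, x, ct;
  for (;;) {
    r1 = unif_rand(); r2 = unif_rand(); r3 = unif_rand();
    if (r1 <= (1.0 + 2.0 * k) / (9.0 + 2.0 * k)) {
      x = 1.0 + 2.0 * k * r2;                 // x = E/E'
      if (r3 <= 4.0 * (1.0 / x - 1.0 / (x * x))) {
        ct = 1.0 - (x - 1.0) / k;
        return ct;
      }
    } else {
      x = (1.0 + 2.0 * k) / (1.0 + 2.0 * k * r2);
      ct = 1.0 - (x - 1.0) / k;
      if (r3 <= 0.5 * (ct * ct + 1.0 / x)) return ct;
    }
  }
}

// Rotate direction u by polar angle (cos ct) and uniform azimuth.
static void rotate_direction(double u[3], double ct) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double phi = 2.0 * M_PI * unif_rand();
  double cp = std::cos(phi), sp = std::sin(phi);
  double ux = u[0], uy = u[1], uz = u[2];
  double nx, ny, nz;
  if (std::fabs(uz) < 0.99999) {
    double den = std::sqrt(1.0 - uz * uz);
    nx = ct * ux + st * (ux * uz * cp - uy * sp) / den;
    ny = ct * uy + st * (uy * uz * cp + ux * sp) / den;
    nz = ct * uz - st * den * cp;
  } else { // nearly along z
    nx = st * cp;
    ny = st * sp;
    nz = ct * (uz > 0 ? 1.0 : -1.0);
  }
  double norm = std::sqrt(nx * nx + ny * ny + nz * nz);
  u[0] = nx / norm; u[1] = ny / norm; u[2] = nz / norm;
}

static void isotropic_direction(double u[3]) {
  double ct = 2.0 * unif_rand() - 1.0;
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double phi = 2.0 * M_PI * unif_rand();
  u[0] = st * std::cos(phi);
  u[1] = st * std::sin(phi);
  u[2] = ct;
}

// Allowed beta-plus spectrum N(T) ~ p * E_tot * (Q - T)^2, Fermi factor ~ 1.
static double beta_density(double T, double Q) {
  double Et = T + ME_C2;
  double p = std::sqrt(std::max(0.0, Et * Et - ME_C2 * ME_C2));
  double q = Q - T;
  return p * Et * q * q;
}

static double beta_sample(double Q, double fmax) {
  for (;;) {
    double T = Q * unif_rand();
    if (unif_rand() * fmax <= beta_density(T, Q)) return T;
  }
}

static double beta_fmax(double Q) {
  double m = 0.0;
  for (int i = 1; i < 512; ++i) {
    double f = beta_density(Q * i / 512.0, Q);
    if (f > m) m = f;
  }
  return m * 1.05;
}

// Uniform point inside a shape.
static void sample_in_shape(const Shape &s, double p[3]) {
  if (s.kind == 0) {
    p[0] = s.c[0] + (2.0 * unif_rand() - 1.0) * s.p1;
    p[1] = s.c[1] + (2.0 * unif_rand() - 1.0) * s.p2;
    p[2] = s.c[2] + (2.0 * unif_rand() - 1.0) * s.p3;
    return;
  }
  int u, v; trans_axes(s.axis, u, v);
  double hl = (s.kind == 1) ? s.p2 : s.p3;
  double axial = (2.0 * unif_rand() - 1.0) * hl;
  double du, dv;
  if (s.kind == 1) {
    double ri2 = s.p3 > 0.0 ? s.p3 * s.p3 : 0.0;
    double r = std::sqrt(ri2 + unif_rand() * (s.p1 * s.p1 - ri2));
    double phi = 2.0 * M_PI * unif_rand();
    du = r * std::cos(phi); dv = r * std::sin(phi);
  } else {
    double r = std::sqrt(unif_rand());
    double phi = 2.0 * M_PI * unif_rand();
    du = s.p1 * r * std::cos(phi); dv = s.p2 * r * std::sin(phi);
  }
  p[s.axis] = s.c[s.axis] + axial;
  p[u] = s.c[u] + du;
  p[v] = s.c[v] + dv;
}

// ---------------------------------------------------------------------------
// Transport of a single photon.  Deposits are credited to the region where
// they occur.  Returns leftover (exiting) energy; fills dep[], counts.
struct TransportCounters {
  int interactions = 0;
  int crossings = 0;
  bool aborted = false;
  double first_interaction_dist = -1.0;
};

static double transport_one(const Scene &sc, const std::vector<MatTab> &mats,
                            double p[3], double d[3], double E,
                            double cutoff, int max_crossings,
                            bool rayleigh, bool interactions,
                            std::vector<double> &dep,
                            TransportCounters &cnt) {
  int reg = locate_point(sc, p);
  double travelled = 0.0;
  while (true) {
    if (reg < 0) return E; // escaped the world
    if (E < cutoff) {      // terminate: deposit locally
      dep[reg] += E;
      return 0.0;
    }
    const MatTab &mt = mats[sc.mat[reg]];
    double mu_pe = 0.0, mu_inc = 0.0, mu_coh = 0.0, mu_t = 0.0;
    if (interactions) {
      mu_pe = interp_mu(mt.logE, mt.pe, E);
      mu_inc = interp_mu(mt.logE, mt.inc, E);
      if (rayleigh) mu_coh = interp_mu(mt.logE, mt.coh, E);
      mu_t = mu_pe + mu_inc + mu_coh;
    }
    double s = (mu_t > 0.0) ? -std::log(unif_rand()) / mu_t : 1e30;
    int next;
    double tb = dist_to_boundary(sc, p, d, reg, &next);
    if (s < tb) {
      p[0] += s * d[0]; p[1] += s * d[1]; p[2] += s * d[2];
      travelled += s;
      if (cnt.interactions == 0) cnt.first_interaction_dist = travelled;
      cnt.interactions++;
      double xi = unif_rand() * mu_t;
      if (xi < mu_pe) {           // photoelectric: full local absorption
        dep[reg] += E;
        return 0.0;
      } else if (xi < mu_pe + mu_inc) { // Compton
        double k = E / ME_C2;
        double ct = kn_sample_costheta(k);
        double Ep = E / (1.0 + k * (1.0 - ct));
        dep[reg] += E - Ep;
        E = Ep;
        rotate_direction(d, ct);
      } else {                    // Rayleigh: elastic, Thomson-like angle
        double ct;
        do { ct = 2.0 * unif_rand() - 1.0; }
        while (unif_rand() > 0.5 * (1.0 + ct * ct));
        rotate_direction(d, ct);
      }
    } else {
      double step = tb + NUDGE;
      p[0] += step * d[0]; p[1] += step * d[1]; p[2] += step * d[2];
      travelled += step;
      reg = next;
      if (++cnt.crossings > max_crossings) { cnt.aborted = true; return E; }
    }
  }
}

// ---------------------------------------------------------------------------
// Exported interfaces
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_locate(NumericMatrix scene, NumericMatrix points) {
  Scene sc = scene_from_matrix(scene);
  int n = points.nrow();
  IntegerVector out(n);
  double p[3];
  for (int i = 0; i < n; ++i) {
    p[0] = points(i, 0); p[1] = points(i, 1); p[2] = points(i, 2);
    out[i] = locate_point(sc, p) + 1; // 1-based, 0 = outside world
  }
  return out;
}

// [[Rcpp::export]]
List cpp_distance_to_boundary(NumericMatrix scene, NumericVector point,
                              NumericVector direction) {
  Scene sc = scene_from_matrix(scene);
  double p[3] = {point[0], point[1], point[2]};
  double d[3] = {direction[0], direction[1], direction[2]};
  int cur = locate_point(sc, p);
  int next;
  double t = dist_to_boundary(sc, p, d, cur, &next);
  return List::create(_["distance"] = t, _["current"] = cur + 1,
                      _["next"] = next + 1);
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_in_shape(NumericVector shape_row, int n) {
  Shape s;
  s.kind = (int)shape_row[0]; s.axis = (int)shape_row[1];
  s.c[0] = shape_row[2]; s.c[1] = shape_row[3]; s.c[2] = shape_row[4];
  s.p1 = shape_row[5]; s.p2 = shape_row[6]; s.p3 = shape_row[7];
  NumericMatrix out(n, 3);
  double p[3];
  for (int i = 0; i < n; ++i) {
    sample_in_shape(s, p);
    out(i, 0) = p[0]; out(i, 1) = p[1]; out(i, 2) = p[2];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_kn(double energy, int n) {
  NumericMatrix out(n, 2); // cols: cos(theta), E'
  double k = energy / ME_C2;
  for (int i = 0; i < n; ++i) {
    double ct = kn_sample_costheta(k);
    out(i, 0) = ct;
    out(i, 1) = energy / (1.0 + k * (1.0 - ct));
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sample_beta(double endpoint, int n) {
  NumericVector out(n);
  double fmax = beta_fmax(endpoint);
  for (int i = 0; i < n; ++i) out[i] = beta_sample(endpoint, fmax);
  return out;
}

// Single interaction given linear channel coefficients: used by the R-level
// step_interaction() so the R surface and the transport loop share one
// sampler.  Returns list(deposit, energy, costheta, alive, channel).
// [[Rcpp::export]]
List cpp_interact(double energy, double mu_pe, double mu_inc, double mu_coh) {
  double mu_t = mu_pe + mu_inc + mu_coh;
  if (mu_t <= 0.0) stop("no interaction channel has positive coefficient");
  double xi = unif_rand() * mu_t;
  if (xi < mu_pe)
    return List::create(_["deposit"] = energy, _["energy"] = 0.0,
                        _["costheta"] = NA_REAL, _["alive"] = false,
                        _["channel"] = "photoelectric");
  if (xi < mu_pe + mu_inc) {
    double k = energy / ME_C2;
    double ct = kn_sample_costheta(k);
    double Ep = energy / (1.0 + k * (1.0 - ct));
    return List::create(_["deposit"] = energy - Ep, _["energy"] = Ep,
                        _["costheta"] = ct, _["alive"] = true,
                        _["channel"] = "incoherent");
  }
  double ct;
  do { ct = 2.0 * unif_rand() - 1.0; }
  while (unif_rand() > 0.5 * (1.0 + ct * ct));
  return List::create(_["deposit"] = 0.0, _["energy"] = energy,
                      _["costheta"] = ct, _["alive"] = true,
                      _["channel"] = "coherent");
}

// [[Rcpp::export]]
List cpp_transport_photon(NumericMatrix scene, List mat_tables,
                          NumericVector position, NumericVector direction,
                          double energy, double cutoff, int max_crossings,
                          bool rayleigh, bool interactions) {
  Scene sc = scene_from_matrix(scene);
  std::vector<MatTab> mats = mats_from_list(mat_tables);
  double p[3] = {position[0], position[1], position[2]};
  double d[3] = {direction[0], direction[1], direction[2]};
  std::vector<double> dep(sc.shapes.size(), 0.0);
  TransportCounters cnt;
  double exitE = transport_one(sc, mats, p, d, energy, cutoff, max_crossings,
                               rayleigh, interactions, dep, cnt);
  return List::create(
      _["deposit_MeV"] = NumericVector(dep.begin(), dep.end()),
      _["exit_MeV"] = exitE, _["n_interactions"] = cnt.interactions,
      _["n_crossings"] = cnt.crossings, _["aborted"] = cnt.aborted,
      _["first_interaction_cm"] = cnt.first_interaction_dist);
}

// Full history batch.
// source: list(type = 0 (F18 decay in source region) | 1 (point photons),
//   region (1-based index of the source region shape; type 0),
//   deterministic_first (bool), beta_fraction, beta_endpoint,
//   point (type 1), energy (type 1))
// [[Rcpp::export]]
List cpp_run_histories(int n, NumericMatrix scene, List mat_tables,
                       List source, double cutoff, int max_crossings,
                       bool rayleigh, bool interactions) {
  Scene sc = scene_from_matrix(scene);
  std::vector<MatTab> mats = mats_from_list(mat_tables);
  int nreg = (int)sc.shapes.size();
  std::vector<double> dep_sum(nreg, 0.0), dep_sq(nreg, 0.0), hist(nreg, 0.0);

  int type = as<int>(source["type"]);
  bool det_first = false;
  double beta_fraction = 1.0, beta_endpoint = 0.6335, fmax = 1.0;
  int src_region = -1;
  double point[3] = {0, 0, 0};
  double point_energy = 0.511;
  if (type == 0) {
    src_region = as<int>(source["region"]) - 1;
    det_first = as<bool>(source["deterministic_first"]);
    beta_fraction = as<double>(source["beta_fraction"]);
    beta_endpoint = as<double>(source["beta_endpoint"]);
    fmax = beta_fmax(beta_endpoint);
  } else {
    NumericVector pt = source["point"];
    point[0] = pt[0]; point[1] = pt[1]; point[2] = pt[2];
    point_energy = as<double>(source["energy"]);
  }

  long n_photons = 0, aborted = 0;
  double exit_sum = 0.0, emitted_sum = 0.0, max_resid = 0.0;

  for (int ih = 0; ih < n; ++ih) {
    hist.assign(nreg, 0.0);
    double emitted = 0.0, exited = 0.0;
    TransportCounters cnt;
    if (type == 0) {
      double pos[3];
      if (ih == 0 && det_first) {
        pos[0] = sc.shapes[src_region].c[0];
        pos[1] = sc.shapes[src_region].c[1];
        pos[2] = sc.shapes[src_region].c[2];
      } else {
        sample_in_shape(sc.shapes[src_region], pos);
      }
      bool beta_branch = unif_rand() < beta_fraction;
      if (beta_branch) {
        (void)beta_sample(beta_endpoint, fmax); // positron KE: not tallied
                                                // (kerma approx., local stop;
                                                // keeps the event stream
                                                // seed-stable)
        double d1[3];
        isotropic_direction(d1);
        for (int g = 0; g < 2; ++g) {
          double p[3] = {pos[0], pos[1], pos[2]};
          double d[3] = {g == 0 ? d1[0] : -d1[0], g == 0 ? d1[1] : -d1[1],
                         g == 0 ? d1[2] : -d1[2]};
          TransportCounters c1;
          double ex = transport_one(sc, mats, p, d, ME_C2, cutoff,
                                    max_crossings, rayleigh, interactions,
                                    hist, c1);
          exited += ex;
          emitted += ME_C2;
          n_photons++;
          if (c1.aborted) aborted++;
        }
      } // EC branch: no photons, history still counted
    } else {
      double p[3] = {point[0], point[1], point[2]};
      double d[3];
      isotropic_direction(d);
      double ex = transport_one(sc, mats, p, d, point_energy, cutoff,
                                max_crossings, rayleigh, interactions, hist,
                                cnt);
      exited += ex;
      emitted += point_energy;
      n_photons++;
      if (cnt.aborted) aborted++;
    }
    double dep_tot = 0.0;
    for (int r = 0; r < nreg; ++r) {
      dep_sum[r] += hist[r];
      dep_sq[r] += hist[r] * hist[r];
      dep_tot += hist[r];
    }
    exit_sum += exited;
    emitted_sum += emitted;
    double resid = std::fabs(emitted - dep_tot - exited);
    if (resid > max_resid) max_resid = resid;
  }

  return List::create(
      _["deposit_MeV"] = NumericVector(dep_sum.begin(), dep_sum.end()),
      _["deposit_sq_MeV2"] = NumericVector(dep_sq.begin(), dep_sq.end()),
      _["histories"] = n, _["n_photons"] = (double)n_photons,
      _["aborted"] = (double)aborted, _["exit_MeV"] = exit_sum,
      _["emitted_MeV"] = emitted_sum, _["max_residual_MeV"] = max_resid);
}
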