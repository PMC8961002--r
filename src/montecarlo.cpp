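// Monte Carlo simulation of restricted diffusion in parametric geometries
// (sphere, finite cylinder, undulating cylinder, ball-and-sticks) with
// specular reflection at the boundaries and PGSE phase accumulation.
//
// Particles take Gaussian steps; a step that would cross the membrane is
// resolved as an elastic collision with the local tangent plane, iterated
// if the reflected step re-crosses.  Phase is accumulated per encoding
// profile as W += u(t_mid) * dx with u(t) the unit-plateau q(t) shape, so
// signals for any b-value and gradient direction follow from W afterwards.
//
// Each particle owns an independent RNG stream derived from the run seed,
// so results are reproducible regardless of scheduling.

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

struct Geom {
  int kind;                       // 0 free, 1 sphere, 2 cylinder, 3 undulating, 4 ball+sticks
  double R, L, A, lam;            // tube radius, length, undulation amplitude/wavelength
  double Rs, Rstick, Lstick;      // ball-and-sticks
  int nst;
  std::vector<double> ux, uy, uz; // stick axis directions (unit)
};

// ---- membership ------------------------------------------------------------

static inline double nearest_s(const Geom &g, const double *p) {
  // arg min_s |p - c(s)|^2 with centerline c(s) = (A sin(ks), 0, s)
  const double k = 2.0 * M_PI / g.lam;
  double s = p[2];
  for (int it = 0; it < 12; ++it) {
    const double sk = std::sin(k * s), ck = std::cos(k * s);
    const double ex = p[0] - g.A * sk;
    const double f1 = -2.0 * g.A * k * ck * ex - 2.0 * (p[2] - s);
    const double f2 = 2.0 * g.A * k * k * sk * ex + 2.0 * g.A * g.A * k * k * ck * ck + 2.0;
    const double stepn = f1 / (std::fabs(f2) > 1e-12 ? f2 : 1e-12);
    s -= stepn;
    if (std::fabs(stepn) < 1e-10) break;
  }
  const double h = 0.5 * g.L;
  if (s > h) s = h;
  if (s < -h) s = -h;
  return s;
}

static inline bool in_stick(const Geom &g, const double *p, int j) {
  const double t = p[0] * g.ux[j] + p[1] * g.uy[j] + p[2] * g.uz[j];
  if (t < 0.0 || t > g.Rs + g.Lstick) return false;
  const double dx = p[0] - t * g.ux[j], dy = p[1] - t * g.uy[j], dz = p[2] - t * g.uz[j];
  return dx * dx + dy * dy + dz * dz < g.Rstick * g.Rstick;
}

static bool inside(const Geom &g, const double *p) {
  switch (g.kind) {
  case 0: return true;
  case 1: return p[0] * p[0] + p[1] * p[1] + p[2] * p[2] < g.R * g.R;
  case 2: return p[0] * p[0] + p[1] * p[1] < g.R * g.R && std::fabs(p[2]) < 0.5 * g.L;
  case 3: {
    if (std::fabs(p[2]) > 0.5 * g.L) return false;
    const double s = nearest_s(g, p);
    const double k = 2.0 * M_PI / g.lam;
    const double ex = p[0] - g.A * std::sin(k * s), ez = p[2] - s;
    return ex * ex + p[1] * p[1] + ez * ez < g.R * g.R;
  }
  case 4: {
    if (p[0] * p[0] + p[1] * p[1] + p[2] * p[2] < g.Rs * g.Rs) return true;
    for (int j = 0; j < g.nst; ++j) if (in_stick(g, p, j)) return true;
    return false;
  }
  }
  return false;
}

// ---- reflection ------------------------------------------------------------

static inline void reflect(double *rem, const double *n) {
  const double d = 2.0 * (rem[0] * n[0] + rem[1] * n[1] + rem[2] * n[2]);
  rem[0] -= d * n[0]; rem[1] -= d * n[1]; rem[2] -= d * n[2];
}

// first exit parameter t in (0, 1] for convex kinds 1-2; returns normal
static bool first_exit_convex(const Geom &g, const double *p0, const double *d,
                              double &tmin, double *n) {
  tmin = 2.0;
  if (g.kind == 1) {
    const double a = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
    if (a <= 0.0) return false;
    const double b = 2.0 * (p0[0] * d[0] + p0[1] * d[1] + p0[2] * d[2]);
    const double c = p0[0] * p0[0] + p0[1] * p0[1] + p0[2] * p0[2] - g.R * g.R;
    const double disc = b * b - 4.0 * a * c;
    if (disc <= 0.0) return false;
    const double t = (-b + std::sqrt(disc)) / (2.0 * a);
    if (t <= 0.0 || t > 1.0) return false;
    tmin = t;
    double px = p0[0] + t * d[0], py = p0[1] + t * d[1], pz = p0[2] + t * d[2];
    const double r = std::sqrt(px * px + py * py + pz * pz);
    n[0] = px / r; n[1] = py / r; n[2] = pz / r;
    return true;
  }
  // finite cylinder: radial wall and caps
  bool hit = false;
  const double a2 = d[0] * d[0] + d[1] * d[1];
  if (a2 > 0.0) {
    const double b = 2.0 * (p0[0] * d[0] + p0[1] * d[1]);
    const double c = p0[0] * p0[0] + p0[1] * p0[1] - g.R * g.R;
    const double disc = b * b - 4.0 * a2 * c;
    if (disc > 0.0) {
      const double t = (-b + std::sqrt(disc)) / (2.0 * a2);
      if (t > 0.0 && t <= 1.0) { tmin = t; hit = true; }
    }
  }
  int cap = 0;
  if (d[2] > 0.0) {
    const double t = (0.5 * g.L - p0[2]) / d[2];
    if (t > 0.0 && t <= 1.0 && t < tmin) { tmin = t; cap = 1; hit = true; }
  } else if (d[2] < 0.0) {
    const double t = (-0.5 * g.L - p0[2]) / d[2];
    if (t > 0.0 && t <= 1.0 && t < tmin) { tmin = t; cap = -1; hit = true; }
  }
  if (!hit) return false;
  if (cap != 0) { n[0] = 0.0; n[1] = 0.0; n[2] = cap; }
  else {
    const double px = p0[0] + tmin * d[0], py = p0[1] + tmin * d[1];
    const double r = std::sqrt(px * px + py * py);
    n[0] = px / r; n[1] = py / r; n[2] = 0.0;
  }
  return true;
}

// boundary normal for the non-convex kinds at a point on (near) the surface
static void surface_normal(const Geom &g, const double *p, double *n) {
  if (g.kind == 3) {
    const double s = nearest_s(g, p);
    const double k = 2.0 * M_PI / g.lam;
    double ex = p[0] - g.A * std::sin(k * s), ey = p[1], ez = p[2] - s;
    const double r = std::sqrt(ex * ex + ey * ey + ez * ez);
    const double dcap = 0.5 * g.L - std::fabs(p[2]);
    if (dcap < std::fabs(g.R - r)) { n[0] = 0; n[1] = 0; n[2] = (p[2] > 0 ? 1.0 : -1.0); }
    else { n[0] = ex / r; n[1] = ey / r; n[2] = ez / r; }
    return;
  }
  // ball and sticks: pick the primitive whose boundary is closest
  double best = 1e30;
  const double rp = std::sqrt(p[0] * p[0] + p[1] * p[1] + p[2] * p[2]);
  best = std::fabs(rp - g.Rs);
  n[0] = p[0] / rp; n[1] = p[1] / rp; n[2] = p[2] / rp;
  for (int j = 0; j < g.nst; ++j) {
    const double t = p[0] * g.ux[j] + p[1] * g.uy[j] + p[2] * g.uz[j];
    if (t < -g.Rstick || t > g.Rs + g.Lstick + g.Rstick) continue;
    const double dx = p[0] - t * g.ux[j], dy = p[1] - t * g.uy[j], dz = p[2] - t * g.uz[j];
    const double rho = std::sqrt(dx * dx + dy * dy + dz * dz);
    const double dwall = std::fabs(rho - g.Rstick);
    if (t >= 0.0 && t <= g.Rs + g.Lstick && dwall < best && rho > 1e-12) {
      best = dwall;
      n[0] = dx / rho; n[1] = dy / rho; n[2] = dz / rho;
    }
    const double dend = std::fabs(t - (g.Rs + g.Lstick));
    if (rho < g.Rstick && dend < best) {
      best = dend;
      n[0] = g.ux[j]; n[1] = g.uy[j]; n[2] = g.uz[j];
    }
  }
}

// resolve one step from x (inside) with proposed displacement dx;
// returns false if the reflection iteration cap is exceeded
static bool resolve_step(const Geom &g, double *x, const double *dx,
                         long long &n_reflect) {
  double p0[3] = {x[0], x[1], x[2]};
  double p1[3] = {x[0] + dx[0], x[1] + dx[1], x[2] + dx[2]};
  if (g.kind == 0) { x[0] = p1[0]; x[1] = p1[1]; x[2] = p1[2]; return true; }

  if (g.kind <= 2) {                       // convex: analytic intersections
    for (int it = 0; it < 50; ++it) {
      if (inside(g, p1)) { x[0] = p1[0]; x[1] = p1[1]; x[2] = p1[2]; return true; }
      double d[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
      double t, n[3];
      if (!first_exit_convex(g, p0, d, t, n)) {
        // endpoint outside but no crossing found (grazing roundoff): clamp
        x[0] = p0[0]; x[1] = p0[1]; x[2] = p0[2]; return true;
      }
      ++n_reflect;
      double pc[3] = {p0[0] + t * d[0], p0[1] + t * d[1], p0[2] + t * d[2]};
      double rem[3] = {p1[0] - pc[0], p1[1] - pc[1], p1[2] - pc[2]};
      reflect(rem, n);
      p0[0] = pc[0] - 1e-9 * n[0]; p0[1] = pc[1] - 1e-9 * n[1]; p0[2] = pc[2] - 1e-9 * n[2];
      p1[0] = p0[0] + rem[0]; p1[1] = p0[1] + rem[1]; p1[2] = p0[2] + rem[2];
    }
    return false;
  }

  // non-convex kinds: if both endpoints are in the union accept the step
  // (single-primitive convex containment covers almost all steps; a step
  // between overlapping primitives stays in the union to within the step
  // size); otherwise locate the boundary by bisection and reflect.
  for (int it = 0; it < 10; ++it) {
    if (inside(g, p1)) { x[0] = p1[0]; x[1] = p1[1]; x[2] = p1[2]; return true; }
    double lo = 0.0, hi = 1.0;
    for (int b = 0; b < 40; ++b) {
      const double mid = 0.5 * (lo + hi);
      double pm[3] = {p0[0] + mid * (p1[0] - p0[0]),
                      p0[1] + mid * (p1[1] - p0[1]),
                      p0[2] + mid * (p1[2] - p0[2])};
      if (inside(g, pm)) lo = mid; else hi = mid;
    }
    ++n_reflect;
    double pc[3] = {p0[0] + lo * (p1[0] - p0[0]),
                    p0[1] + lo * (p1[1] - p0[1]),
                    p0[2] + lo * (p1[2] - p0[2])};
    double n[3];
    surface_normal(g, pc, n);
    double rem[3] = {p1[0] - pc[0], p1[1] - pc[1], p1[2] - pc[2]};
    // make sure the normal opposes the outgoing remainder
    if (rem[0] * n[0] + rem[1] * n[1] + rem[2] * n[2] < 0.0) {
      n[0] = -n[0]; n[1] = -n[1]; n[2] = -n[2];
    }
    reflect(rem, n);
    p0[0] = pc[0]; p0[1] = pc[1]; p0[2] = pc[2];
    p1[0] = p0[0] + rem[0]; p1[1] = p0[1] + rem[1]; p1[2] = p0[2] + rem[2];
    if (!inside(g, p0)) break;             // lost the surface: give up
  }
  return false;
}

// ---- initial positions -----------------------------------------------------

static void init_position(const Geom &g, std::mt19937_64 &rng, double *p) {
  std::uniform_real_distribution<double> U(-1.0, 1.0);
  std::uniform_real_distribution<double> U01(0.0, 1.0);
  switch (g.kind) {
  case 0:
    p[0] = p[1] = p[2] = 0.0; return;
  case 1:
    do { p[0] = g.R * U(rng); p[1] = g.R * U(rng); p[2] = g.R * U(rng); }
    while (!inside(g, p));
    return;
  case 2:
    do { p[0] = g.R * U(rng); p[1] = g.R * U(rng); p[2] = 0.5 * g.L * U(rng); }
    while (!inside(g, p));
    return;
  case 3: {
    const double bx = g.A + g.R;
    do { p[0] = bx * U(rng); p[1] = g.R * U(rng); p[2] = 0.5 * g.L * U(rng); }
    while (!inside(g, p));
    return;
  }
  case 4: {
    // sample primitives by volume with multiplicity correction (exact
    // uniform sampling of the union)
    const double Vs = 4.0 * M_PI / 3.0 * g.Rs * g.Rs * g.Rs;
    const double Vst = M_PI * g.Rstick * g.Rstick * g.Lstick;
    const double Vtot = Vs + g.nst * Vst;
    for (;;) {
      const double pick = U01(rng) * Vtot;
      if (pick < Vs) {
        do { p[0] = g.Rs * U(rng); p[1] = g.Rs * U(rng); p[2] = g.Rs * U(rng); }
        while (p[0] * p[0] + p[1] * p[1] + p[2] * p[2] >= g.Rs * g.Rs);
      } else {
        const int j = std::min((int)((pick - Vs) / Vst), g.nst - 1);
        const double t = g.Rs + U01(rng) * g.Lstick;
        double rho, a, bq;
        do { a = g.Rstick * U(rng); bq = g.Rstick * U(rng); rho = a * a + bq * bq; }
        while (rho >= g.Rstick * g.Rstick);
        // orthonormal frame around u_j
        double e1[3], e2[3];
        const double u0 = g.ux[j], u1 = g.uy[j], u2 = g.uz[j];
        if (std::fabs(u0) < 0.9) { e1[0] = 0; e1[1] = -u2; e1[2] = u1; }
        else { e1[0] = -u1; e1[1] = u0; e1[2] = 0; }
        double nrm = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
        e1[0] /= nrm; e1[1] /= nrm; e1[2] /= nrm;
        e2[0] = u1 * e1[2] - u2 * e1[1];
        e2[1] = u2 * e1[0] - u0 * e1[2];
        e2[2] = u0 * e1[1] - u1 * e1[0];
        p[0] = t * u0 + a * e1[0] + bq * e2[0];
        p[1] = t * u1 + a * e1[1] + bq * e2[1];
        p[2] = t * u2 + a * e1[2] + bq * e2[2];
      }
      int mult = (p[0] * p[0] + p[1] * p[1] + p[2] * p[2] < g.Rs * g.Rs) ? 1 : 0;
      for (int j = 0; j < g.nst; ++j) if (in_stick(g, p, j)) ++mult;
      if (mult < 1) continue;              // roundoff edge: resample
      if (mult == 1 || U01(rng) < 1.0 / mult) return;
    }
  }
  }
}

// ---- main driver -----------------------------------------------------------

// [[Rcpp::export]]
List mc_simulate_cpp(int kind, NumericVector gp, NumericMatrix stick_dirs,
                     int n_particles, int n_steps, double step_sd,
                     NumericMatrix uprof, int seed) {
  Geom g;
  g.kind = kind;
  g.R = g.L = g.A = g.lam = g.Rs = g.Rstick = g.Lstick = 0.0;
  g.nst = 0;
  if (kind == 1) g.R = gp[0];
  else if (kind == 2) { g.R = gp[0]; g.L = gp[1]; }
  else if (kind == 3) { g.R = gp[0]; g.L = gp[1]; g.A = gp[2]; g.lam = gp[3]; }
  else if (kind == 4) {
    g.Rs = gp[0]; g.Rstick = gp[1]; g.Lstick = gp[2];
    g.nst = stick_dirs.nrow();
    g.ux.resize(g.nst); g.uy.resize(g.nst); g.uz.resize(g.nst);
    for (int j = 0; j < g.nst; ++j) {
      g.ux[j] = stick_dirs(j, 0); g.uy[j] = stick_dirs(j, 1); g.uz[j] = stick_dirs(j, 2);
    }
  }

  const int n_prof = uprof.nrow();         // uprof: n_prof x n_steps
  if (uprof.ncol() != n_steps) stop("uprof must be n_profiles x n_steps");

  NumericMatrix W(n_particles, 3 * n_prof);
  NumericMatrix start(n_particles, 3), end(n_particles, 3);
  long long n_reflect = 0;
  int n_fail = 0, n_escaped = 0;
  std::vector<double> ucol(n_prof * (size_t)n_steps);
  for (int s = 0; s < n_steps; ++s)
    for (int p = 0; p < n_prof; ++p) ucol[(size_t)s * n_prof + p] = uprof(p, s);

  for (int i = 0; i < n_particles; ++i) {
    std::mt19937_64 rng(splitmix64(((uint64_t)seed << 20) + (uint64_t)i));
    std::normal_distribution<double> N(0.0, step_sd);
    double x[3];
    init_position(g, rng, x);
    start(i, 0) = x[0]; start(i, 1) = x[1]; start(i, 2) = x[2];
    std::vector<double> w(3 * n_prof, 0.0);
    bool ok = true;
    for (int s = 0; s < n_steps; ++s) {
      double dx[3] = {N(rng), N(rng), N(rng)};
      double x0[3] = {x[0], x[1], x[2]};
      if (!resolve_step(g, x, dx, n_reflect)) { ok = false; }
      const double *u = &ucol[(size_t)s * n_prof];
      for (int p = 0; p < n_prof; ++p) {
        const double up = u[p];
        if (up != 0.0) {
          w[3 * p] += up * (x[0] - x0[0]);
          w[3 * p + 1] += up * (x[1] - x0[1]);
          w[3 * p + 2] += up * (x[2] - x0[2]);
        }
      }
    }
    if (!ok) ++n_fail;
    if (!inside(g, x)) ++n_escaped;
    for (int p = 0; p < 3 * n_prof; ++p) W(i, p) = w[p];
    end(i, 0) = x[0]; end(i, 1) = x[1]; end(i, 2) = x[2];
  }

  return List::create(_["W"] = W, _["start"] = start, _["end"] = end,
                      _["n_reflect"] = (double)n_reflect,
                      _["n_fail"] = n_fail, _["n_escaped"] = n_escaped);
}

// signal from accumulated phase weights: S(b) averaged over particles and
// directions, per profile; qmax = sqrt(b / (Delta - delta/3)) supplied by R
// [[Rcpp::export]]
NumericVector mc_signal_cpp(NumericMatrix W, int profile, NumericMatrix dirs,
                            NumericVector qmax, IntegerVector particles) {
  const int nb = qmax.size(), nd = dirs.nrow(), np = particles.size();
  NumericVector out(nb);
  for (int ib = 0; ib < nb; ++ib) {
    double acc = 0.0;
    for (int ii = 0; ii < np; ++ii) {
      const int i = particles[ii] - 1;
      const double wx = W(i, 3 * profile), wy = W(i, 3 * profile + 1),
                   wz = W(i, 3 * profile + 2);
      for (int d = 0; d < nd; ++d) {
        const double phi = qmax[ib] *
          (dirs(d, 0) * wx + dirs(d, 1) * wy + dirs(d, 2) * wz);
        acc += std::cos(phi);
      }
    }
    out[ib] = acc / ((double)np * nd);
  }
  return out;
}
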