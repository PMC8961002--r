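// Stepped matrix-exponential solver for the generalized two-compartment
// Karger rate equations along a rectangular-pulse PGSE encoding.
//
//   d/dt [S1; S2] = (K - q^2(t) diag(D1, D2)) [S1; S2],  K = [-r1 r2; r1 -r2]
//
// q(t) is piecewise linear (up ramp / plateau / down ramp).  Each ramp is
// split into n_ramp substeps and advanced with exp(K h - diag(D) Iq) where
// Iq is the analytic integral of q^2 over the substep (second-order Magnus
// truncation; exact on the plateau and whenever K and diag(D) commute).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// apply exp(M) of the 2x2 matrix [[m11,m12],[m21,m22]] to (s1,s2) in place;
// off-diagonal entries are non-negative here so the eigenvalues are real
static inline void expm2_apply(double m11, double m12, double m21, double m22,
                               double &s1, double &s2) {
  const double tr = m11 + m22;
  const double disc = (m11 - m22) * (m11 - m22) + 4.0 * m12 * m21;
  const double sq = std::sqrt(disc > 0.0 ? disc : 0.0);
  const double a = s1, b = s2;
  if (sq > 1e-13 * (std::fabs(m11) + std::fabs(m22) + 1.0)) {
    const double l1 = 0.5 * (tr + sq), l2 = 0.5 * (tr - sq);
    const double e1 = std::exp(l1), e2 = std::exp(l2);
    const double d = l1 - l2;
    const double p11 = (m11 - l2) / d, p12 = m12 / d;
    const double p21 = m21 / d, p22 = (m22 - l2) / d;
    s1 = e1 * (p11 * a + p12 * b) + e2 * ((1.0 - p11) * a - p12 * b);
    s2 = e1 * (p21 * a + p22 * b) + e2 * (-p21 * a + (1.0 - p22) * b);
  } else {                                  // (nearly) degenerate eigenvalues
    const double l = 0.5 * tr;
    const double e = std::exp(l);
    s1 = e * (a + (m11 - l) * a + m12 * b);
    s2 = e * (b + m21 * a + (m22 - l) * b);
  }
}

// fourth-order Magnus substep for A(t) = K - q^2(t) diag(D1, D2):
//   Omega = K h - F diag(D) + (sqrt(3) h^2 / 12)(f2 - f1) [K, diag(D)]
// with f1, f2 = q^2 at the two Gauss points and F = (f1 + f2) h / 2 (exact
// for the quadratic q^2 on a ramp); [K, diag(D)] = [[0, r2 (D2 - D1)],
// [r1 (D1 - D2), 0]].
static inline void magnus4_step(double h, double fg1, double fg2,
                                double D1, double D2, double r1, double r2,
                                double &s1, double &s2) {
  const double F = 0.5 * (fg1 + fg2) * h;
  const double c = std::sqrt(3.0) * h * h * (fg2 - fg1) / 12.0;
  expm2_apply(-r1 * h - D1 * F, r2 * (h + c * (D2 - D1)),
              r1 * (h + c * (D1 - D2)), -r2 * h - D2 * F, s1, s2);
}

// advance one full encoding for fixed (D1, D2, r1, r2) from (f1, f2)
static double karger_sequence(double b, double Delta, double delta,
                              double D1, double D2, double f1,
                              double r1, double r2, int n_ramp) {
  double s1 = f1, s2 = 1.0 - f1;
  if (b <= 0.0) return s1 + s2;
  const double q2max = b / (Delta - delta / 3.0);
  const double h = delta / n_ramp;
  const double g1 = 0.5 - std::sqrt(3.0) / 6.0, g2 = 0.5 + std::sqrt(3.0) / 6.0;
  // up ramp: q^2(t) = q2max (t/delta)^2
  for (int i = 0; i < n_ramp; ++i) {
    const double t0 = i * h;
    const double ta = (t0 + g1 * h) / delta, tb = (t0 + g2 * h) / delta;
    magnus4_step(h, q2max * ta * ta, q2max * tb * tb, D1, D2, r1, r2, s1, s2);
  }
  // plateau (constant generator: exact)
  const double hp = Delta - delta;
  if (hp > 0.0) {
    const double Iq = q2max * hp;
    expm2_apply(-r1 * hp - D1 * Iq, r2 * hp, r1 * hp, -r2 * hp - D2 * Iq, s1, s2);
  }
  // down ramp: q^2(t) = q2max ((T - t)/delta)^2, T = Delta + delta
  for (int i = 0; i < n_ramp; ++i) {
    const double t0 = Delta + i * h;
    const double ta = (Delta + delta - (t0 + g1 * h)) / delta;
    const double tb = (Delta + delta - (t0 + g2 * h)) / delta;
    magnus4_step(h, q2max * ta * ta, q2max * tb * tb, D1, D2, r1, r2, s1, s2);
  }
  return s1 + s2;
}

// [[Rcpp::export]]
NumericVector karger_pgse_cpp(NumericVector b, NumericVector Delta,
                              NumericVector delta, double D1, double D2,
                              double f1, double r1, double r2, int n_ramp) {
  const int n = b.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = karger_sequence(b[i], Delta[i], delta[i], D1, D2, f1, r1, r2, n_ramp);
  return out;
}

// Powder-averaged stick--extracellular exchange signal: compartment 1 is a
// stick with apparent diffusivity Dn eps^2 along gradient direction eps,
// integrated over eps in [0,1] with the supplied quadrature rule.
// [[Rcpp::export]]
NumericVector karger_powder_cpp(NumericVector b, NumericVector Delta,
                                NumericVector delta, double Dn, double De,
                                double fn, double rn, double re,
                                NumericVector eps, NumericVector w,
                                int n_ramp) {
  const int n = b.size(), m = eps.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int k = 0; k < m; ++k)
      acc += w[k] * karger_sequence(b[i], Delta[i], delta[i],
                                    Dn * eps[k] * eps[k], De, fn, rn, re,
                                    n_ramp);
    out[i] = acc;
  }
  return out;
}
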