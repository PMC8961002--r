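# MR soma-radius estimators under radius distributions and the
# permeability--residence-time relation.

#' Gamma soma-radius distribution
#'
#' Parameterized by mean and standard deviation (shape `k = (mean/sd)^2`,
#' scale `theta = sd^2/mean`); `sd = 0` is treated as a point mass.
#'
#' @param mean Mean radius, um.
#' @param sd Standard deviation, um (>= 0).
#' @return Object of class `"radius_distribution"`.
#' @export
radius_distribution <- function(mean, sd) {
  if (mean <= 0 || sd < 0) stop("need mean > 0 and sd >= 0")
  structure(list(family = "gamma", mean = mean, sd = sd,
                 shape = if (sd > 0) (mean / sd)^2 else Inf,
                 scale = if (sd > 0) sd^2 / mean else 0),
            class = "radius_distribution")
}

#' Raw moments of the radius distribution
#'
#' Closed-form gamma moments `<R^n> = theta^n Gamma(k + n)/Gamma(k)`;
#' a point mass returns `mean^n`.
#'
#' @param dist A [radius_distribution()].
#' @param n Moment order (vectorized, need not be integer).
#' @return `<R^n>` in um^n.
#' @export
gamma_moment <- function(dist, n) {
  stopifnot(inherits(dist, "radius_distribution"))
  if (dist$sd == 0) return(dist$mean^n)
  dist$scale^n * exp(lgamma(dist$shape + n) - lgamma(dist$shape))
}

#' Moment-ratio MR radius for small compartments
#'
#' Closed-form effective MR radii implied by volume weighting and the
#' diffusivity's radius dependence in the small-compartment limits:
#' * `"axon"`: `(<R^6>/<R^2>)^(1/4)` (radial diffusivity ~ R^4, cylinder
#'   volume weighting R^2)
#' * `"soma_small_wide_pulse"`: `(<R^7>/<R^3>)^(1/4)` (somas with
#'   `Delta D >> R^2`)
#' * `"soma_small_narrow_pulse"`: `(<R^5>/<R^3>)^(1/2)` (somas with
#'   `delta D << R^2`, diffusivity ~ R^2)
#'
#' @param dist A [radius_distribution()].
#' @param regime One of the three regimes above.
#' @return Effective MR radius, um.
#' @export
moment_ratio_radius <- function(dist,
                                regime = c("soma_small_narrow_pulse",
                                           "soma_small_wide_pulse", "axon")) {
  regime <- match.arg(regime)
  switch(regime,
    axon = (gamma_moment(dist, 6) / gamma_moment(dist, 2))^(1 / 4),
    soma_small_wide_pulse = (gamma_moment(dist, 7) / gamma_moment(dist, 3))^(1 / 4),
    soma_small_narrow_pulse = (gamma_moment(dist, 5) / gamma_moment(dist, 3))^(1 / 2))
}

#' Expected MR radius of a soma-radius distribution
#'
#' Averages the narrow-pulse sphere diffusivity over the distribution with
#' soma-volume (`R^3`) weighting and inverts the monotone map `R -> Ds(R)`
#' back to the single radius producing the same diffusivity.  The
#' alternative definition matching the volume-weighted *signal*
#' `exp(-b Ds)` at a reference b-value is available via
#' `weighting = "signal"`.
#'
#' @param dist A [radius_distribution()].
#' @param Delta Diffusion time, ms (default 16).
#' @param D0 Intra-soma free diffusivity, um^2/ms (default 2).
#' @param weighting `"diffusivity"` (default) or `"signal"`.
#' @param b Reference b-value for `weighting = "signal"`, ms/um^2.
#' @return Effective MR radius, um.
#' @export
expected_mr_radius <- function(dist, Delta = 16, D0 = 2,
                               weighting = c("diffusivity", "signal"), b = 1) {
  stopifnot(inherits(dist, "radius_distribution"))
  weighting <- match.arg(weighting)
  roots <- sphere_roots()
  Ds <- function(R) sphere_diffusivity_narrow_pulse(Delta, R, D0, roots)
  if (dist$sd == 0) return(dist$mean)
  upper <- dist$mean + 8 * dist$sd
  w <- function(R) R^3 * dgamma(R, shape = dist$shape, scale = dist$scale)
  den <- integrate(w, 0, upper, rel.tol = 1e-9)$value
  target <- if (weighting == "diffusivity") {
    integrate(function(R) Ds(R) * w(R), 0, upper, rel.tol = 1e-9)$value / den
  } else {
    Sbar <- integrate(function(R) exp(-b * Ds(R)) * w(R), 0, upper,
                      rel.tol = 1e-9)$value / den
    -log(Sbar) / b
  }
  hi <- upper
  if (Ds(hi) < target) stop("inversion target outside the monotone range")
  uniroot(function(R) Ds(R) - target, c(1e-3, hi), tol = 1e-10)$root
}

#' Membrane permeability from residence time (well-mixed cylinder)
#'
#' In the well-mixed (barrier-limited) regime the escape rate relates to
#' permeability through the surface-to-volume ratio, `1/tau = P S/V`; for a
#' cylinder `S/V = 2/R`, giving `P = R/(2 tau)`.
#'
#' @param R Cylinder (neurite) radius, um.
#' @param tau Residence time, ms.
#' @return Permeability in um/s.
#' @export
permeability_from_residence <- function(R, tau) {
  if (any(R <= 0) || any(tau <= 0)) stop("'R' and 'tau' must be positive")
  1000 * R / (2 * tau)   # um/ms -> um/s
}
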