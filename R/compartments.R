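# Elementary non-exchanging compartment signals: isotropic Gaussian,
# powder-averaged stick, and Gaussian-phase sphere diffusivities.

#' Isotropic Gaussian compartment signal
#'
#' @param b Diffusion weighting, ms/um^2 (vectorized).
#' @param D Diffusivity, um^2/ms.
#' @return `exp(-b D)` as a fraction of S0.
#' @export
gaussian_signal <- function(b, D) {
  if (any(b < 0) || any(D < 0)) stop("'b' and 'D' must be non-negative")
  exp(-b * D)
}

#' Powder-averaged stick signal
#'
#' Spherical mean of a zero-radius cylinder ("stick") compartment,
#' `sqrt(pi/(4 b Dn)) erf(sqrt(b Dn))`, which approaches the `b^(-1/2)`
#' power-law at large `b Dn` and 1 as `b Dn -> 0` (evaluated by series for
#' small arguments to avoid 0/0).
#'
#' @param b Diffusion weighting, ms/um^2 (vectorized).
#' @param Dn Intra-neurite (axial) diffusivity, um^2/ms.
#' @return Signal fraction of S0 in (0, 1].
#' @export
stick_powder_signal <- function(b, Dn) {
  if (any(b < 0) || any(Dn < 0)) stop("'b' and 'Dn' must be non-negative")
  x <- b * Dn
  s <- numeric(length(x))
  small <- x < 1e-4
  # int_0^1 exp(-x e^2) de = sum_k (-x)^k / (k! (2k+1))
  s[small] <- 1 - x[small] / 3 + x[small]^2 / 10 - x[small]^3 / 42
  xl <- x[!small]
  s[!small] <- sqrt(pi / (4 * xl)) * pracma::erf(sqrt(xl))
  s
}

#' Dimensionless eigenvalue spectrum for diffusion in a sphere
#'
#' The positive roots of `J_{3/2}(a) = a J_{5/2}(a)` (equivalently
#' `j1'(a) = 0`, the reflecting-boundary condition for the radial modes of a
#' sphere; the first root is 2.081576).  Roots are found by bracketed
#' bisection to 1e-12 and cached per truncation order.
#'
#' @param M Truncation order (number of roots).  The default retains enough
#'   terms that doubling `M` changes the sphere diffusivities by less than
#'   1e-8 across Delta in \[5, 30\] ms and R in \[1, 20\] um.
#' @return Numeric vector of the first `M` roots, strictly increasing.
#' @export
sphere_roots <- function(M = 400) {
  key <- paste0("roots", M)
  if (!is.null(.sandix_cache[[key]])) return(.sandix_cache[[key]])
  f <- function(a) besselJ(a, 3 / 2) - a * besselJ(a, 5 / 2)
  roots <- numeric(M)
  # roots are close to 2.0816 + (m-1) pi; bracket each with a +-1 window
  for (m in seq_len(M)) {
    lo <- if (m == 1) 1.5 else roots[m - 1] + 2
    hi <- 2.0815759778 + (m - 1) * pi + 1.2
    r <- uniroot(f, c(lo, hi), tol = 1e-12)
    roots[m] <- r$root
  }
  if (any(diff(roots) <= 0)) stop("sphere spectrum root finding failed")
  .sandix_cache[[key]] <- roots
  roots
}

#' Narrow-pulse sphere diffusivity
#'
#' Apparent diffusivity of water restricted in an impermeable sphere in the
#' narrow-pulse limit,
#' `Ds = (2 R^2 / Delta) sum_m (1/(a_m^2 (a_m^2 - 2))) (1 - exp(-a_m^2 D0 Delta / R^2))`,
#' with `a_m` the sphere spectrum roots.  As `Delta -> Inf`,
#' `Ds -> R^2 / (5 Delta)` (the variance of the displacement between two
#' independent uniform points in the ball over `2 Delta`).
#'
#' @param Delta Diffusion time (pulse separation), ms.
#' @param R Sphere radius, um.
#' @param D0 Free (intra-sphere) diffusivity, um^2/ms; default 2.
#' @param roots Optional precomputed [sphere_roots()].
#' @return Apparent diffusivity in um^2/ms, in `(0, D0)`.
#' @export
sphere_diffusivity_narrow_pulse <- function(Delta, R, D0 = 2, roots = sphere_roots()) {
  if (any(R <= 0) || any(Delta <= 0)) stop("'R' and 'Delta' must be positive")
  vapply(seq_along(R), function(i) {
    a2 <- roots^2
    (2 * R[i]^2 / Delta) *
      sum((1 - exp(-a2 * D0 * Delta / R[i]^2)) / (a2 * (a2 - 2)))
  }, numeric(1))
}

#' Finite-pulse (Gaussian phase) sphere diffusivity
#'
#' Apparent diffusivity such that the sphere signal is `exp(-b Ds)` for a
#' rectangular-pulse PGSE encoding, from the Gaussian phase approximation
#' sum over the sphere eigenmodes:
#' `b Ds = g^2 gamma^2 sum_m (B_m / a_m^2) psi_m(delta, Delta)` with
#' `B_m = 2 R^2 / (alpha_m^2 (alpha_m^2 - 2))`, decay rates
#' `a_m = alpha_m^2 D0 / R^2` and the usual rectangular-pulse kernel
#' `psi_m = 2 a_m delta - 2 + 2 e^(-a_m delta) + 2 e^(-a_m Delta)
#'  - e^(-a_m (Delta - delta)) - e^(-a_m (Delta + delta))`.
#' Reduces to [sphere_diffusivity_narrow_pulse()] as `delta -> 0`.
#'
#' @inheritParams sphere_diffusivity_narrow_pulse
#' @param delta Gradient pulse width, ms; `0 < delta <= Delta`.
#' @return Apparent diffusivity in um^2/ms.
#' @export
sphere_diffusivity_gpa <- function(Delta, delta, R, D0 = 2, roots = sphere_roots()) {
  if (any(R <= 0)) stop("'R' must be positive")
  if (any(delta <= 0) || any(Delta <= 0) || any(delta > Delta))
    stop("need 0 < delta <= Delta")
  vapply(seq_along(R), function(i) {
    a2 <- roots^2
    am <- a2 * D0 / R[i]^2
    Bm <- 2 * R[i]^2 / (a2 * (a2 - 2))
    psi <- 2 * am * delta - 2 + 2 * exp(-am * delta) + 2 * exp(-am * Delta) -
      exp(-am * (Delta - delta)) - exp(-am * (Delta + delta))
    sum(Bm * psi / am^2) / (delta^2 * (Delta - delta / 3))
  }, numeric(1))
}
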