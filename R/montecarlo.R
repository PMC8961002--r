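# Monte Carlo diffusion simulation in parametric restricted geometries with
# PGSE signal synthesis and apparent-exponent analysis.

#' Parametric Monte Carlo geometries
#'
#' Constructors for the supported restricted geometries (all lengths in um):
#' a sphere, a finite cylinder with end caps, a tube around a sinusoidal
#' centerline ("undulating cylinder"), and a "toy neuron" of a spherical
#' soma with thin cylindrical sticks attached at its surface along
#' deterministic, uniformly spread orientations.
#'
#' @param R,L Radius and length of the sphere/cylinder/tube.
#' @param amplitude,wavelength Undulation amplitude and wavelength
#'   (`amplitude < wavelength/2`).
#' @param R_soma,n_sticks,R_stick,L_stick Ball-and-sticks parameters.
#' @return An object of class `"mc_geometry"`.
#' @name mc_geometry
NULL

#' @rdname mc_geometry
#' @export
mc_sphere <- function(R) {
  stopifnot(R > 0)
  structure(list(kind = "sphere", code = 1L, gp = R, dirs = matrix(0, 0, 3),
                 R_min = R), class = "mc_geometry")
}

#' @rdname mc_geometry
#' @export
mc_cylinder <- function(R, L) {
  stopifnot(R > 0, L > 0)
  structure(list(kind = "cylinder", code = 2L, gp = c(R, L),
                 dirs = matrix(0, 0, 3), R_min = R), class = "mc_geometry")
}

#' @rdname mc_geometry
#' @export
mc_undulating_cylinder <- function(R, L, amplitude = 1, wavelength = 20) {
  stopifnot(R > 0, L > 0, amplitude >= 0, wavelength > 0)
  if (amplitude >= wavelength / 2)
    stop("undulation amplitude must be below wavelength/2")
  structure(list(kind = "undulating_cylinder", code = 3L,
                 gp = c(R, L, amplitude, wavelength),
                 dirs = matrix(0, 0, 3), R_min = R), class = "mc_geometry")
}

#' @rdname mc_geometry
#' @export
mc_ball_and_sticks <- function(R_soma, n_sticks, R_stick, L_stick) {
  stopifnot(R_soma > 0, n_sticks >= 1, R_stick > 0, L_stick > 0)
  structure(list(kind = "ball_and_sticks", code = 4L,
                 gp = c(R_soma, R_stick, L_stick),
                 dirs = mc_directions(n_sticks, hemisphere = FALSE),
                 R_min = R_stick), class = "mc_geometry")
}

#' Deterministic uniformly spread unit directions
#'
#' Fibonacci-lattice points on the (hemi)sphere; used for stick orientations
#' and powder-average direction sets.
#'
#' @param n Number of directions.
#' @param hemisphere Restrict to the upper hemisphere (default `TRUE`, the
#'   powder-average convention).
#' @return `n x 3` matrix of unit vectors.
#' @export
mc_directions <- function(n, hemisphere = TRUE) {
  i <- seq_len(n) - 0.5
  z <- if (hemisphere) i / n else 1 - 2 * i / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Monte Carlo run configuration
#'
#' @param n_particles Number of particles.
#' @param sigma Typical step size, um; the time step is
#'   `dt = sigma^2/(6 D0)` so free diffusion reproduces `D0`.  Must satisfy
#'   `sigma <= R_min/10` for the geometry simulated.
#' @param D0 Free diffusivity, um^2/ms (default 2).
#' @param duration Total simulated time, ms (at least the encoding length).
#'   `dt` is adjusted slightly so that `dt * n_steps = duration` exactly.
#' @param seed RNG seed; every particle derives its own stream from it.
#' @return Object of class `"mc_config"`.
#' @export
mc_config <- function(n_particles = 10000, sigma = 0.05, D0 = 2,
                      duration, seed = 1) {
  stopifnot(n_particles >= 1, sigma > 0, D0 > 0, duration > 0)
  dt0 <- sigma^2 / (6 * D0)
  n_steps <- ceiling(duration / dt0)
  dt <- duration / n_steps
  structure(list(n_particles = as.integer(n_particles), sigma = sqrt(6 * D0 * dt),
                 D0 = D0, duration = duration, dt = dt,
                 n_steps = as.integer(n_steps), seed = as.integer(seed)),
            class = "mc_config")
}

# unit-plateau q(t) shape for one (delta, Delta) profile at step midpoints
.profile_u <- function(delta, Delta, dt, n_steps) {
  t <- (seq_len(n_steps) - 0.5) * dt
  u <- numeric(n_steps)
  up <- t < delta
  flat <- t >= delta & t <= Delta
  down <- t > Delta & t <= Delta + delta
  u[up] <- t[up] / delta
  u[flat] <- 1
  u[down] <- (Delta + delta - t[down]) / delta
  u
}

#' Run a Monte Carlo diffusion simulation
#'
#' Simulates Gaussian random walks with specular (elastic) reflection at the
#' geometry boundary, accumulating for every encoding profile the
#' q-weighted displacement `W = sum u(t_mid) dx` per particle, from which
#' [mc_signal()] synthesizes PGSE signals for any b-value and direction set.
#'
#' @param geom An `"mc_geometry"` object.
#' @param cfg An [mc_config()]; `cfg$duration` must cover every profile's
#'   `Delta + delta`.
#' @param profiles Data frame with columns `delta`, `Delta` (ms), one row
#'   per encoding profile.
#' @return Object of class `"mc_run"` with the weight matrix, start/end
#'   positions, reflection statistics and the containment check.
#' @export
mc_simulate <- function(geom, cfg, profiles) {
  stopifnot(inherits(geom, "mc_geometry"), inherits(cfg, "mc_config"))
  profiles <- as.data.frame(profiles)
  stopifnot(all(c("delta", "Delta") %in% names(profiles)))
  if (any(profiles$Delta + profiles$delta > cfg$duration + 1e-9))
    stop("cfg$duration must be at least Delta + delta for every profile")
  if (geom$code != 0L && cfg$sigma > geom$R_min / 10)
    stop("step size must satisfy sigma <= R_min/10 for this geometry")
  uprof <- t(vapply(seq_len(nrow(profiles)), function(i)
    .profile_u(profiles$delta[i], profiles$Delta[i], cfg$dt, cfg$n_steps),
    numeric(cfg$n_steps)))
  # cfg$sigma is the rms 3D step; each Cartesian component gets sigma/sqrt(3)
  res <- mc_simulate_cpp(geom$code, geom$gp, geom$dirs, cfg$n_particles,
                         cfg$n_steps, cfg$sigma / sqrt(3), uprof, cfg$seed)
  if (res$n_fail > 0)
    warning(sprintf("reflection iteration cap exceeded for %d particle steps",
                    res$n_fail))
  if (res$n_escaped > 0)
    warning(sprintf("%d particles ended outside the geometry", res$n_escaped))
  structure(list(W = res$W, start = res$start, end = res$end,
                 n_reflect = res$n_reflect, n_fail = res$n_fail,
                 n_escaped = res$n_escaped, geom = geom, cfg = cfg,
                 profiles = profiles), class = "mc_run")
}

#' @export
print.mc_run <- function(x, ...) {
  cat(sprintf("MC run: %s, %d particles, %d steps (dt = %.3g ms), %d profile(s)\n",
              x$geom$kind, x$cfg$n_particles, x$cfg$n_steps, x$cfg$dt,
              nrow(x$profiles)))
  invisible(x)
}

#' Synthesize powder-averaged PGSE signals from a Monte Carlo run
#'
#' `S(b) = <cos(q_max d . W)>` averaged over particles and a uniform
#' direction set, where `W` is the accumulated q-weighted displacement for
#' the chosen profile.
#'
#' @param run An [mc_simulate()] result.
#' @param b Vector of b-values, ms/um^2.
#' @param profile Index into `run$profiles`.
#' @param directions Direction count (uniform hemisphere, >= 30 recommended)
#'   or an explicit `n x 3` matrix.
#' @param particles Optional particle index subset (default all).
#' @return A `"powder_signal"` table with provenance `"synthetic"`.
#' @export
mc_signal <- function(run, b, profile = 1, directions = 30, particles = NULL) {
  stopifnot(inherits(run, "mc_run"))
  dirs <- if (is.matrix(directions)) directions else mc_directions(directions)
  if (is.null(particles)) particles <- seq_len(nrow(run$W))
  delta <- run$profiles$delta[profile]; Delta <- run$profiles$Delta[profile]
  qmax <- sqrt(b / (Delta - delta / 3))
  S <- mc_signal_cpp(run$W, as.integer(profile - 1), dirs, qmax,
                     as.integer(particles))
  signal_table(b, Delta, delta, S, provenance = "synthetic")
}

#' Apparent diffusivity along a direction from a Monte Carlo run
#'
#' Narrow-pulse-style ADC from the endpoint displacements:
#' `ADC = var(d . (end - start)) / (2 duration)`.
#'
#' @param run An [mc_simulate()] result.
#' @param direction Unit 3-vector (default z-axis).
#' @return ADC in um^2/ms.
#' @export
mc_adc <- function(run, direction = c(0, 0, 1)) {
  d <- direction / sqrt(sum(direction^2))
  disp <- (run$end - run$start) %*% d
  mean(disp^2) / (2 * run$cfg$duration)
}

#' Split a ball-and-sticks run into soma and neurite sub-signals
#'
#' Particles starting farther than `R_soma + 2 sqrt(2 D0 t)` from the soma
#' center are labelled neurite; the remainder make up the soma signal.
#' Particles between the soma surface and the threshold are geometrically in
#' the sticks but may encounter the soma during the encoding; their share of
#' the soma-labelled population is reported.
#'
#' @param run An [mc_simulate()] result on an `mc_ball_and_sticks` geometry.
#' @param b Vector of b-values for the sub-signals.
#' @param t Diffusion time entering the threshold, ms (default the
#'   profile's `Delta`).
#' @param profile Profile index.
#' @param directions Direction count or matrix for the powder average.
#' @return List with `neurite` and `soma` signal tables, the particle
#'   counts, and `in_between_fraction`.
#' @export
soma_neurite_split <- function(run, b, t = NULL, profile = 1, directions = 30) {
  stopifnot(inherits(run, "mc_run"))
  if (run$geom$kind != "ball_and_sticks")
    stop("the soma/neurite split requires a ball_and_sticks geometry")
  Rs <- run$geom$gp[1]; Lstick <- run$geom$gp[3]
  if (is.null(t)) t <- run$profiles$Delta[profile]
  thr <- Rs + 2 * sqrt(2 * run$cfg$D0 * t)
  if (thr > Rs + Lstick) stop("split threshold exceeds the stick length")
  r0 <- sqrt(rowSums(run$start^2))
  neur <- which(r0 > thr)
  soma <- which(r0 <= thr)
  if (length(neur) == 0 || length(soma) == 0)
    stop("degenerate split: adjust geometry or threshold time")
  list(
    neurite = mc_signal(run, b, profile, directions, particles = neur),
    soma = mc_signal(run, b, profile, directions, particles = soma),
    n_neurite = length(neur), n_soma = length(soma),
    in_between_fraction = sum(r0 > Rs & r0 <= thr) / length(soma),
    threshold = thr)
}

#' Apparent power-law exponent over a grid of pulse times
#'
#' Runs a single simulation covering every `(delta, Delta)` combination and
#' evaluates the apparent exponent (log-log slope over b in \[10, 100\]
#' ms/um^2) of the powder-averaged signal per combination.
#'
#' @param geom An `"mc_geometry"`.
#' @param cfg An [mc_config()] whose duration covers `max(Delta) + max(delta)`
#'   (it is extended automatically if not).
#' @param delta_list,Delta_list Pulse-time grids, ms (small grids, <= 5 x 5).
#' @param b Vector of b-values for the exponent fit (>= 4 values in
#'   \[10, 100\]).
#' @param directions Powder direction count.
#' @return Matrix of exponents, rows = `delta_list`, columns = `Delta_list`,
#'   with the `mc_run` attached as attribute `"run"`.
#' @export
exponent_map <- function(geom, cfg, delta_list, Delta_list,
                         b = seq(0.4, 0.1, by = -0.05)^-2, directions = 30) {
  grid <- expand.grid(delta = delta_list, Delta = Delta_list)
  grid <- grid[grid$delta <= grid$Delta, , drop = FALSE]
  need <- max(grid$Delta + grid$delta)
  if (cfg$duration < need)
    cfg <- mc_config(cfg$n_particles, cfg$sigma, cfg$D0, need, cfg$seed)
  run <- mc_simulate(geom, cfg, grid)
  expo <- matrix(NA_real_, length(delta_list), length(Delta_list),
                 dimnames = list(delta = delta_list, Delta = Delta_list))
  for (i in seq_len(nrow(grid))) {
    tab <- mc_signal(run, b, profile = i, directions = directions)
    expo[as.character(grid$delta[i]), as.character(grid$Delta[i])] <-
      powerlaw_exponent(tab)
  }
  structure(expo, run = run)
}
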