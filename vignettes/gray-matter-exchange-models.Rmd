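---
title: "Modelling gray-matter diffusion MRI with neurite water exchange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gray-matter diffusion MRI with neurite water exchange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sandix)
```

# Scope and units

`sandix` models the *powder-averaged* (spherical-mean) diffusion MRI signal
of gray matter as a sum of water compartments — extracellular water,
neurites (sticks), somas (spheres) and an immobile offset — with optional
first-order water exchange between the sticks and the extracellular pool.
Everything operates on ROI-averaged signal curves `S(b, Δ, δ)/S0`, not on
image volumes. Units are fixed package-wide: times in ms, lengths in μm,
b-values in ms/μm², diffusivities in μm²/ms; the gyromagnetic ratio appears
only when a PGSE encoding is converted to a physical gradient amplitude.

# The signal models and their assumptions

## Non-exchanging compartments

The extracellular pool is an isotropic Gaussian, `exp(−b·De)`. Neurites are
sticks — zero-radius cylinders whose spherical mean is
`sqrt(π/(4·b·Dn))·erf(sqrt(b·Dn))`, approaching the `b^(−1/2)` power law at
large `b·Dn`. Somas are impermeable spheres treated in the Gaussian phase
approximation (GPA): the signal is `exp(−b·Ds(Δ, δ, Rs))` with the apparent
diffusivity assembled from the sphere eigenmodes, whose dimensionless
eigenvalues solve `J_{3/2}(α) = α·J_{5/2}(α)` (equivalently `j1'(α) = 0`;
first root 2.081576). The narrow-pulse form is

`Ds = (2R²/Δ) Σ_m (1/(α_m²(α_m²−2))) (1 − exp(−α_m² D0 Δ / R²))`,

and the finite-pulse form uses the standard rectangular-pulse kernel over
the same modes; the two agree as δ → 0, which is the test that pins the
root convention. The GPA is applied at *all* b-values: once the soma signal
deviates from the GPA it is so attenuated that the neurite signal dominates,
so the error is immaterial for the total — the Monte Carlo module, which
contains the full restricted physics, is the oracle backing this
approximation at moderate b.

Key fixed parameter: the intra-soma free diffusivity `D0 = 2 μm²/ms`. The
fitted quantities are only weakly sensitive to it, and fixing it removes a
near-degenerate direction from the fit.

## Exchange: the generalized Kärger engine

Exchange between sticks and extracellular water is modelled by two Gaussian
pools coupled by rates obeying detailed balance (`rn·fn = re·fe`), valid
when exchange is barrier-limited (spins explore their compartment between
exchange events). For an arbitrary piecewise-linear `q(t)` the coupled rate
equations are advanced per orientation cosine ε (the stick's apparent
diffusivity along the gradient is `Dn·ε²`) and powder-averaged with a
64-node Gauss–Legendre rule on [0, 1]; the rule's adequacy is checked by
order doubling at b = 100 ms/μm², the largest supported weighting. Each
spin is assumed to visit only one neurite during an encoding, so the many-
orientation system factorizes into identical two-pool "cells" — an
approximation that is strained by very fast exchange.

Two solvers implement the same equations:

* `karger_ode_signal()` — adaptive Runge–Kutta (deSolve, rtol 1e-9,
  atol 1e-12), integrating segment-by-segment so the solver sees the kinks
  of q(t); the reference route.
* `karger_signal()` / the C++ engine behind `stick_exchange_powder()` — a
  stepped 2×2 matrix-exponential scheme: exact on the gradient plateau
  (where the generator is constant) and fourth-order Magnus on the ramps
  (two Gauss nodes per substep with a closed-form commutator term). With
  the default 64 substeps per ramp the relative error is ~1e-7; fitting
  uses 32 substeps (~1e-6), far below any noise floor. The test suite
  cross-checks both routes against a 10⁴-step product of matrix
  exponentials built on `Matrix::expm`, an implementation independent of
  either.

The narrow-pulse closed form is evaluated in the overflow-safe factored
form `exp(−a2)·[(1+e^(−2h))/2 − u(1−e^(−2h))/(2h)]`, `h = s/2`, which
covers the degenerate-exponent case by its series limit. Its exact time
derivative at fixed b is

`dS/dt = −(f1·r1/2)(b·D1 − b·D2)² exp(−(a1+a2)/2) (h·cosh h − sinh h)/h³`,

which is non-positive for every parameter choice — the *exchange
signature*. The prefactor and the `s/2` argument were fixed by matching the
analytic derivative of the closed form itself; the suite verifies the match
against central finite differences on a thousand random parameter draws and
asserts the sign everywhere.

The large-b expansion implemented in `karger_largeb_series()` is
`fn·sqrt(π/(4 b Dn))·e^(−t·rn)·(1 + t·re/(b·De) + …)`: the stick power-law
amplitude is attenuated by the fraction of non-exchanged neurite water with
corrections of higher order in 1/b. A b-independent term inside the bracket
would change the b → ∞ limit and contradict the parent closed form (whose
exact asymptote the tests verify numerically), so none is included. The
companion estimator `exchange_rate_quadratic()` fits
`ln(S(t0+t)/S(t0)) = −c1·t − c2·t²` at one large b-value and returns
`rn = c1 − 2·t0·c2`; it assumes `t0·re ≫ 1` and a sufficiently large b, and
flags (but does not enforce) violations.

## Model assembly

* SANDI: `fe·gauss + fn·stick + fs·sphere + fim` (no exchange),
* SMEX: exchanging block of weight `fe + fn` plus `fim`,
* SANDIX: SMEX + sphere,
* eSANDIX: SANDIX + an impermeable stick population sharing `Dn`.

`fim` is a b- and time-independent offset included in the sum-to-one
constraint. SMEX and SANDIX bracket the truth with respect to soma
exchange (fully permeable vs impermeable somas). Setting `tau_n = Inf`
reduces SMEX to SANDI without a soma *exactly* (the engine short-circuits
to the analytic no-exchange sum), which the nesting tests exploit.

# The functional signatures

`powerlaw_exponent()` is the absolute OLS slope of `ln S` vs `ln b` over
b ∈ [10, 100] ms/μm² — 0.5 for sticks, > 1 for Gaussian decay in that
window. `time_dependence_sign()` compares signals across Δ at each shared
b-value with a relative dead-band of 0.5% (motivated by the ~1% residual
noise of averaged ex vivo curves): comparisons inside the dead-band do not
vote, and the classification is "decreasing" (exchange-dominated),
"increasing" (structure-dominated) or "mixed". With exact b-matching
required across Δ — the acquisition is designed so shells share b-values —
no interpolation is ever performed.

# Fitting

`fit_model()` runs bounded Levenberg–Marquardt (minpack.lm, ftol/ptol
1e-12) from uniform random starts inside the initialization box:
diffusivities 0–3 μm²/ms, exchange rate 0–1 ms⁻¹ (reported as
`tau_n = 1/rn`), soma radius 0–20 μm, and the exchanging pair's relative
fraction 0–100%. The linear amplitudes (compartment fractions times S0)
are eliminated at every objective evaluation by non-negative least squares
(`pracma::lsqnonneg`), i.e. variable projection; rank-deficient bases fall
back to a small ridge and are flagged. The immobile fraction is capped at
5% by an active-set substitution, a choice motivated by consistently
sub-1% estimates for this offset; residuals are unweighted since noise is
handled upstream by Rician bias correction. The default 50 starts keep the
examples and tests fast; production fits should use several hundred to a
thousand. Converged solutions are clustered into basins at 1% relative
parameter tolerance (with a small absolute floor for parameters near zero)
and ranked by cost; `BIC = n·ln(cost/n) + k·ln(n)` with k counting
nonlinear parameters plus linear amplitudes, computed identically across
models, and ΔBIC > 10 / < 1 flagged as significant / indistinguishable.

Identical seed and data give bit-identical results. A characteristic
behaviour worth knowing: on noisy data the sphere and Gaussian columns are
nearly collinear when `Ds(Rs) ≈ De`, producing a competing basin that
trades a smaller soma radius against a larger extracellular diffusivity.
The basin enumeration exists precisely to surface this degeneracy rather
than hide it.

# The synthetic-data generator

`generate_dataset()` emulates the package's reference acquisition: pulse
width 4.5 ms; separations 7.5, 11, 16 ms; seven low-b shells
(0.1–5 ms/μm²) per separation plus dense high-b shells generated linearly
in `b^(−1/2)` from the printed endpoints and steps (11, 12 and 21 shells
respectively, the last with halved spacing below 0.3 μm/ms^(1/2)); 10
averages for b ≤ 25 ms/μm² and 30 above; 30 gradient directions per shell.
Rician magnitude noise of standard deviation σ per channel is applied to
every direction of every average, the magnitudes are averaged, and the
Rician bias is removed by numerically inverting the first-moment relation
`ν ↦ σ·sqrt(π/2)·L_{1/2}(−ν²/2σ²)` at the known per-measurement σ (the
mean of n Rician draws keeps the single-draw first moment). Means at or
below the zero-signal floor `σ·sqrt(π/2)` are clamped to zero and flagged.

What the generator does *not* emulate: directional signal variation within
a shell (there is no orientation distribution — each direction carries the
powder-averaged value, so the direction count only sets the effective noise
level), spatially varying noise, residual denoising artifacts, and any
structural time dependence beyond the soma term. Passing recovery tests on
this generator therefore demonstrates correctness of the estimation
machinery under the stated noise model, not robustness to every property of
real data. The b = 0.1 ms/μm² point is included for all separations and
flagged via the protocol's `lowest_b` attribute.

At σ = 0.01 per measurement the effective noise on an averaged powder
point is 0.03–0.06% of S0. Diagnostics during development showed this is
the regime in which the exchange models' parameters are recoverable to
~15%; with the same σ applied directly at the powder level (effective
noise ~0.2–0.3%) the global minimum genuinely migrates in the
(fe, Dn) plane while `tau_n` remains stable — the residence time is the
robust quantity, consistent with the degeneracy discussion above.

# Monte Carlo simulator

The Rcpp simulator draws Gaussian steps (rms 3D step σ, time step
`dt = σ²/(6·D0)`) and resolves boundary crossings as elastic collisions
with the local tangent plane, iterated when the reflected step re-crosses.
Sphere and cylinder use exact ray-surface intersections; the undulating
tube (a tube of radius R around a sinusoidal centerline) and the
ball-and-sticks neuron locate the crossing by bisection on membership and
take the normal from the nearest primitive surface. Initial positions are
exactly uniform: rejection sampling for the convex bodies and the tube,
and volume-weighted primitive sampling with multiplicity correction for
the ball-and-sticks union. Per-particle RNG streams are derived from the
run seed (splitmix64 into mt19937_64), so results are reproducible and
independent of scheduling. Phase is accumulated per encoding profile as
`W += u(t_mid)·Δx` with `u(t)` the unit-plateau q(t) shape and `Δx` the
net step displacement (exact for piecewise-constant q over a step);
signals for any b and direction set follow as `⟨cos(q_max·d·W)⟩`, so one
run serves every b-value.

Desk-scale defaults are σ = 0.05 μm and 10³–10⁴ particles; convergence is
demonstrated by the step-halving property (halving σ leaves signals at
b ≤ 100 unchanged within the runs' sampling error plus a 1% bias
allowance) rather than by cluster-scale particle counts. The
soma/neurite split of a toy-neuron run labels as "neurite" the particles
starting farther than `R_soma + 2·sqrt(2·D0·t)` from the soma center and
reports the fraction of soma-labelled particles that are geometrically in
the sticks. Two geometric approximations are documented rather than
hidden: steps whose endpoints lie in two different overlapping primitives
of a non-convex union may clip the concave junction notch (an effect below
the step size), and the undulating tube's end faces are flat cuts. The
undulation defaults (amplitude 1 μm, wavelength 20 μm) are illustrative
surrogates for realistic neurite meandering, not calibrated values.

# MR radius analysis

For a gamma distribution of soma radii (mean m, sd s; shape `(m/s)²`,
scale `s²/m`), `moment_ratio_radius()` returns the closed-form
volume-weighting overestimates for small compartments —
`(<R⁶>/<R²>)^(1/4)` for axons, `(<R⁷>/<R³>)^(1/4)` for small somas with
wide pulses, `(<R⁵>/<R³>)^(1/2)` for small somas with narrow pulses — and
`expected_mr_radius()` handles the realistic case where somas are *not*
small: it averages the narrow-pulse sphere diffusivity over the
distribution with R³ volume weighting and inverts the monotone map
R → Ds(R) back to a single matching radius (adaptive quadrature over
[0, m + 8s], tolerance 1e-9). The alternative definition that matches the
volume-weighted *signal* at a reference b is provided behind
`weighting = "signal"`; it depends on the chosen b (it equals the
diffusivity-weighted definition as b → 0), which is why the b-free
diffusivity-weighted form is the default. All estimators exceed the
distribution mean whenever the variance is positive.

`permeability_from_residence()` converts a residence time to a membrane
permeability in the well-mixed regime via the surface-to-volume ratio of a
cylinder, `P = R/(2τ)`, reported in μm/s.

# Numerical choices, in one place

* Sphere spectrum: 400 roots by bracketed bisection (tolerance 1e-12),
  cached. The α^(−4) tail of the narrow-pulse sum needs this many terms
  for the doubling-stability property (< 1e-8 change on Δ ∈ [5, 30] ms,
  R ∈ [1, 20] μm) to hold at the large-R, short-Δ corner; the cost is a
  few milliseconds once per session.
* Stick signal: series below `b·Dn = 1e-4` to avoid 0/0.
* Powder quadrature: 64 Gauss–Legendre nodes on [0, 1]; doubling changes
  the b = 100 average by < 1e-6.
* Karger stepping: plateau exact; ramps Magnus-4 with exact `∫q² dt` per
  substep; 64 substeps (signal paths) / 32 (fitting).
* Narrow-pulse closed forms: factored exponential forms against overflow;
  series limits at `h < 1e-8` (signal) and `h < 1e-4` (derivative).
* Optimizer: trust-region LM, ftol/ptol 1e-12, max 300 iterations;
  non-finite basis values yield a large finite cost instead of an error.
* Monte Carlo: reflection iteration caps (50 analytic / 10 bisection) with
  failures counted and reported, never silently absorbed; `dt` adjusted so
  `dt·n_steps` equals the requested duration exactly.

# Problem sizes used by the tests

The suite exercises the full three-separation acquisition (65 powder
points) for model fits with 25–50 random starts, Monte Carlo runs of
10³–10⁴ particles (the thin-cylinder power-law check uses 10⁴ particles at
σ = 0.05 μm), and 10³-point random grids for the derivative and sign
properties. These sizes were chosen so the whole suite completes on a
single CPU in well under half an hour while keeping every statistical
tolerance at least three standard errors wide.

# Known limitations

* The Kärger description omits spatiotemporal coupling; at residence times
  of a few ms the barrier-limited assumption is itself under strain, and
  the one-neurite-per-spin factorization degrades in the same regime.
* The GPA soma term ignores localization-regime physics; it is validated
  against Monte Carlo only at moderate b.
* Exchange between somas and anything is neglected by construction; SMEX
  vs SANDIX comparisons gauge the impact.
* The generator's noise model is powder-level Rician per direction; truly
  directional data with orientation dispersion is out of scope.
* Signal fractions are T1/T2-weighted quantities, not volume fractions;
  nothing in the package attempts relaxation correction.
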