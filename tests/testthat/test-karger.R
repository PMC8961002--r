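test_that("exchange pairs satisfy detailed balance", {
  p <- exchange_pair(0.5, 1.1, 0.65, 0.25)
  expect_equal(p$r1 * p$f1, p$r2 * p$f2, tolerance = 1e-12)
  expect_equal(p$Dbar, 0.65 * 0.5 + 0.35 * 1.1)
})

test_that("ODE and stepped solvers agree with the matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  pair <- exchange_pair(D1 = 0.5, D2 = 1.0, f1 = 0.6, r1 = 0.25)
  for (b in c(2, 10, 25)) {
    s <- pgse(b, 16, 4.5)
    oracle <- matexp_oracle(s, pair, n_steps = 1e4)
    expect_lt(abs(karger_ode_signal(s, pair) - oracle), 1e-8)
    expect_lt(abs(karger_signal(s, pair) - oracle), 1e-8)
  }
})

test_that("exchange-free and equal-diffusivity cases are exact", {
  s <- pgse(10, 16, 4.5)
  p0 <- exchange_pair(0.5, 1.0, 0.6, 0)
  expect_equal(karger_signal(s, p0), 0.6 * exp(-5) + 0.4 * exp(-10),
               tolerance = 1e-14)
  pD <- exchange_pair(1, 1, 0.6, 0.3)   # exchange invisible when D1 = D2
  expect_equal(karger_signal(s, pD), exp(-10), tolerance = 1e-13)
  expect_lt(abs(karger_ode_signal(s, pD) - exp(-10)), 1e-9)
})

test_that("mass is conserved at zero diffusion weighting", {
  s0 <- pgse(0, 16, 4.5)
  p <- exchange_pair(0.5, 1.0, 0.3, 0.8)
  expect_equal(karger_signal(s0, p), 1, tolerance = 1e-14)
  expect_equal(karger_ode_signal(s0, p), 1, tolerance = 1e-10)
})

test_that("narrow-pulse closed form matches the ODE in the narrow-pulse limit", {
  pair <- exchange_pair(D1 = 0.5, D2 = 1.0, f1 = 0.6, r1 = 0.25)
  Delta <- 16; delta <- Delta * 1e-3
  for (b in c(5, 25)) {
    s <- pgse(b, Delta, delta)
    closed <- karger_narrow_pulse(b, Delta - delta / 3, pair)$S
    expect_equal(closed, karger_ode_signal(s, pair), tolerance = 1e-4)
  }
})

test_that("narrow-pulse solution is normalized and reduces to a biexponential", {
  pair <- exchange_pair(0.4, 1.2, 0.55, 0.3)
  sol <- karger_narrow_pulse(c(0, 7, 40), 16, pair)
  expect_equal(sol$fp1 + sol$fp2, rep(1, 3))
  expect_equal(sol$S[1], 1)
  p0 <- exchange_pair(0.4, 1.2, 0.55, 0)
  expect_equal(karger_narrow_pulse(7, 16, p0)$S,
               0.55 * exp(-7 * 0.4) + 0.45 * exp(-7 * 1.2), tolerance = 1e-12)
  # degenerate a1 = a2 handled by the analytic limit
  pdg <- exchange_pair(1, 1, 0.5, 0)
  expect_equal(karger_narrow_pulse(3, 16, pdg)$S, exp(-3), tolerance = 1e-12)
})

test_that("closed-form time derivative is non-positive and matches finite differences", {
  set.seed(42)
  n_bad_sign <- 0
  for (i in 1:1000) {
    b <- runif(1, 0.5, 80); t <- runif(1, 2, 40)
    pair <- exchange_pair(runif(1, 0.05, 2.5), runif(1, 0.05, 2.5),
                          runif(1, 0.05, 0.95), runif(1, 0.005, 0.8))
    d <- karger_time_derivative(b, t, pair)
    if (d > 0) n_bad_sign <- n_bad_sign + 1
    h <- 1e-4 * t
    fd <- (karger_narrow_pulse(b, t + h, pair)$S -
           karger_narrow_pulse(b, t - h, pair)$S) / (2 * h)
    expect_equal(d, fd, tolerance = 1e-6)
  }
  expect_equal(n_bad_sign, 0)
  # structural zeros
  expect_equal(karger_time_derivative(10, 16, exchange_pair(1, 1, 0.5, 0.3)), 0)
  expect_equal(karger_time_derivative(10, 16, exchange_pair(0.4, 1, 0.5, 0)), 0)
  expect_equal(karger_time_derivative(10, 16, exchange_pair(0.4, 1, 0, 0.3)), 0)
})

test_that("large-b series approximates the powder-integrated closed form", {
  # exchange-free limit: exact stick power-law term
  expect_equal(karger_largeb_series(100, 16, 0.5, 1, 0.6, 0, 0),
               0.6 * sqrt(pi / (4 * 100 * 0.5)))
  # slow exchange: within 5% of the quadrature over the closed form
  fn <- 0.6; rn <- 1 / 50; re <- rn * fn / (1 - fn)
  series <- karger_largeb_series(100, 16, 0.5, 1, fn, rn, re)
  oracle <- np_powder_oracle(100, 16, 0.5, 1, fn, rn)
  expect_equal(series, oracle, tolerance = 0.05)
  # ratio converges monotonically to 1 as b grows
  bgrid <- 10^seq(log10(50), log10(5000), length.out = 12)
  ratio <- vapply(bgrid, function(b)
    karger_largeb_series(b, 16, 0.5, 1, fn, rn, re) /
      np_powder_oracle(b, 16, 0.5, 1, fn, rn), numeric(1))
  expect_true(all(diff(abs(ratio - 1)) < 0))
  expect_lt(abs(ratio[length(ratio)] - 1), 1e-3)
  expect_warning(karger_largeb_series(5, 16, 0.5, 1, fn, rn, re), "b\\*Dn")
})

test_that("powder-averaged exchange signal reduces to its analytic limits", {
  b <- c(5, 20, 100)
  # no exchange: analytic stick + gaussian mixture
  expect_equal(stick_exchange_powder(b, 16, 4.5, 2, 1, 0.5, 0),
               0.5 * stick_powder_signal(b, 2) + 0.5 * gaussian_signal(b, 1))
  # fast-exchange surrogate: per-orientation fully mixed diffusivity
  fe_lim <- vapply(b, function(bb)
    integrate(function(e) exp(-bb * (0.5 * 1.5 * e^2 + 0.5 * 0.85)), 0, 1,
              rel.tol = 1e-12)$value, numeric(1))
  got <- stick_exchange_powder(b, 16, 4.5, 1.5, 0.85, 0.5, 1000)
  expect_equal(got, fe_lim, tolerance = 0.01)
})

test_that("finite-pulse powder signal approaches the narrow-pulse integral as delta shrinks", {
  b <- 100; Delta <- 16
  target <- np_powder_oracle(b, Delta, 0.5, 0.85, 0.5, 0.25)
  s1 <- stick_exchange_powder(b, Delta, 4.5, 0.5, 0.85, 0.5, 0.25)
  s2 <- stick_exchange_powder(b, Delta, 2.25, 0.5, 0.85, 0.5, 0.25)
  # halving delta at least halves the gap to the narrow-pulse value
  expect_lt(abs(s2 - target), 0.5 * abs(s1 - target) + 1e-12)
  expect_lt(abs(s1 - target) / target, 0.2)
})

test_that("powder quadrature is stable under order doubling at the largest b", {
  a64 <- stick_exchange_powder(100, 16, 4.5, 0.5, 0.85, 0.6, 0.25,
                               quad = powder_quadrature(64))
  a128 <- stick_exchange_powder(100, 16, 4.5, 0.5, 0.85, 0.6, 0.25,
                                quad = powder_quadrature(128))
  expect_lt(abs(a64 - a128) / a128, 1e-6)
  expect_equal(sum(powder_quadrature(64)$weights), 1, tolerance = 1e-12)
})

test_that("exchange rate is recovered from the quadratic time dependence", {
  # signals generated from the large-b series with known slow exchange
  rn <- 1 / 50; fn <- 0.8; re <- rn * fn / (1 - fn)
  b <- 100; De <- 1; t0 <- 20
  times <- t0 + c(0, 2, 4, 6, 8)
  S <- karger_largeb_series(b, times, 0.5, De, fn, rn, re)
  est <- exchange_rate_quadratic(times, S, b, De)
  expect_equal(est$rn, rn, tolerance = 0.1)
  # time-independent input gives a zero rate
  est0 <- exchange_rate_quadratic(times, rep(0.3, 5), b, De)
  expect_equal(est0$rn, 0, tolerance = 1e-12)
  # noisy input: median recovery bias is bounded and nothing crashes
  set.seed(7)
  ests <- replicate(100, {
    Sn <- S * (1 + rnorm(5, 0, 0.01))
    suppressWarnings(exchange_rate_quadratic(times, Sn, b, De)$rn)
  })
  expect_lt(abs(median(ests) - rn) / rn, 0.5)
})

test_that("karger signals decrease with b and with diffusion time", {
  pair <- exchange_pair(0.6, 1.0, 0.55, 0.2)
  b <- seq(0, 100, by = 5)
  S <- karger_narrow_pulse(b, 16, pair)$S
  expect_true(all(diff(S) < 0))
  expect_true(all(S > 0 & S <= 1))
  for (b0 in c(5, 25, 80)) {
    St <- vapply(c(7.5, 11, 16, 24), function(t)
      karger_narrow_pulse(b0, t, pair)$S, numeric(1))
    expect_true(all(diff(St) < 0))
    # the PGSE engine shows the same monotone decrease with Delta
    Se <- vapply(c(7.5, 11, 16, 24), function(t)
      karger_signal(pgse(b0, t, 4.5), pair), numeric(1))
    expect_true(all(diff(Se) < 0))
  }
})
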