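test_that("free diffusion reproduces the nominal diffusivity", {
  cfg <- mc_config(n_particles = 3000, sigma = 0.1, D0 = 2, duration = 10,
                   seed = 3)
  geof <- structure(list(kind = "free", code = 0L, gp = 0,
                         dirs = matrix(0, 0, 3), R_min = Inf),
                    class = "mc_geometry")
  run <- mc_simulate(geof, cfg, data.frame(delta = 1, Delta = 8))
  adc <- mc_adc(run)
  se <- sqrt(2 / cfg$n_particles) * 2
  expect_lt(abs(adc - 2), 3 * se)
})

test_that("sphere statistics match the uniform-ball displacement variance", {
  cfg <- mc_config(n_particles = 4000, sigma = 0.2, D0 = 2, duration = 40,
                   seed = 4)
  run <- mc_simulate(mc_sphere(7), cfg, data.frame(delta = 0.2, Delta = 30))
  expect_equal(run$n_escaped, 0)      # containment
  expect_equal(run$n_fail, 0)
  msd <- mean((run$end[, 1] - run$start[, 1])^2)
  se <- sd((run$end[, 1] - run$start[, 1])^2) / sqrt(cfg$n_particles)
  expect_lt(abs(msd - 2 * 49 / 5), max(0.02 * 2 * 49 / 5, 3 * se))
  # long-run density stays uniform: equal-volume radial bins
  r3 <- rowSums(run$end^2)^(3 / 2) / 7^3
  counts <- table(cut(r3, seq(0, 1, by = 0.1)))
  p <- suppressWarnings(stats::chisq.test(counts)$p.value)
  expect_gt(p, 0.01)
  # narrow-pulse ADC at small b matches the eigenmode sum within 2%
  tab <- mc_signal(run, b = 0.2, profile = 1, directions = 30)
  adc <- -log(tab$S[1]) / 0.2
  expect_equal(adc, sphere_diffusivity_narrow_pulse(30, 7, 2),
               tolerance = 0.02)
})

test_that("cylinder diffusion is free along the axis and b=0 gives S=1", {
  cfg <- mc_config(n_particles = 2000, sigma = 0.05, D0 = 2, duration = 8,
                   seed = 5)
  run <- mc_simulate(mc_cylinder(0.5, 200), cfg,
                     data.frame(delta = 1, Delta = 6))
  adc_ax <- mc_adc(run, c(0, 0, 1))
  se <- sqrt(2 / cfg$n_particles) * 2
  expect_lt(abs(adc_ax - 2), 3 * se)
  tab <- mc_signal(run, b = c(0, 5), profile = 1)
  expect_identical(tab$S[tab$b == 0], 1)
  expect_equal(run$n_escaped, 0)
})

test_that("finite-pulse sphere signal follows the GPA diffusivity at small b", {
  cfg <- mc_config(n_particles = 4000, sigma = 0.5, D0 = 2, duration = 20.5,
                   seed = 6)
  run <- mc_simulate(mc_sphere(12), cfg, data.frame(delta = 4.5, Delta = 16))
  tab <- mc_signal(run, b = 0.25, profile = 1, directions = 30)
  adc <- -log(tab$S[1]) / 0.25
  expect_equal(adc, sphere_diffusivity_gpa(16, 4.5, 12, 2), tolerance = 0.05)
})

test_that("halving the step size leaves signals unchanged within sampling error", {
  b <- c(10, 40, 100)
  runs <- lapply(c(0.1, 0.05), function(sg) {
    cfg <- mc_config(n_particles = 3000, sigma = sg, D0 = 2, duration = 10.5,
                     seed = 7)
    mc_simulate(mc_cylinder(1, 100), cfg, data.frame(delta = 2, Delta = 8.5))
  })
  # block standard errors over particle subsets; the two runs use disjoint
  # random streams, so the discretization bias must hide below the combined
  # noise plus a 1% allowance
  block_se <- function(run) {
    blocks <- split(seq_len(nrow(run$W)), rep(1:10, length.out = nrow(run$W)))
    S <- vapply(blocks, function(i) mc_signal(run, b, particles = i)$S,
                numeric(length(b)))
    apply(S, 1, sd) / sqrt(length(blocks))
  }
  s1 <- mc_signal(runs[[1]], b)$S
  s2 <- mc_signal(runs[[2]], b)$S
  se <- sqrt(block_se(runs[[1]])^2 + block_se(runs[[2]])^2)
  expect_true(all(abs(s1 - s2) < 3 * se + 0.01 * s2))
})

test_that("toy neuron splits into stick-like neurites and obscuring soma", {
  run <- toy_neuron_run()
  expect_equal(run$n_escaped, 0)
  # reflection-cap hits must be vanishingly rare
  expect_lt(run$n_fail / (run$cfg$n_particles * run$cfg$n_steps), 1e-6)
  b <- seq(0.316, 0.1, length.out = 8)^-2    # 10 to 100 ms/um^2
  split <- soma_neurite_split(run, b)
  # neurite sub-signal follows the stick power-law; total is steeper
  e_neur <- powerlaw_exponent(split$neurite)
  total <- mc_signal(run, b)
  e_tot <- powerlaw_exponent(total)
  expect_lt(e_neur, 0.62)
  expect_gt(e_tot, e_neur)
  # neurite signal dominates the total at the largest b
  expect_gt(split$neurite$S[length(b)] * split$n_neurite,
            0.5 * total$S[length(b)] * nrow(run$W))
  # few particles sit between the soma surface and the threshold
  expect_lt(split$in_between_fraction, 0.12)
  # threshold -> 0 limit equals geometric membership
  s0 <- soma_neurite_split(run, b, t = 1e-8)
  r0 <- sqrt(rowSums(run$start^2))
  expect_equal(s0$n_neurite, sum(r0 > 8))
})

test_that("a single-cell exponent map equals the direct exponent call", {
  geom <- mc_cylinder(1, 100)
  cfg <- mc_config(n_particles = 1200, sigma = 0.1, D0 = 2, duration = 13,
                   seed = 8)
  b <- seq(0.316, 0.12, length.out = 6)^-2
  m <- exponent_map(geom, cfg, delta_list = 2, Delta_list = 11, b = b)
  run <- attr(m, "run")
  expect_equal(dim(m), c(1L, 1L))
  expect_equal(m[1, 1], powerlaw_exponent(mc_signal(run, b, profile = 1)))
})

test_that("undulating thin cylinders still scale like sticks", {
  geom <- mc_undulating_cylinder(0.25, 120, amplitude = 1, wavelength = 20)
  cfg <- mc_config(n_particles = 800, sigma = 0.025, D0 = 2, duration = 13,
                   seed = 9)
  run <- suppressWarnings(mc_simulate(geom, cfg, data.frame(delta = 2, Delta = 11)))
  expect_equal(run$n_escaped, 0)
  expect_lt(run$n_fail / (run$cfg$n_particles * run$cfg$n_steps), 1e-6)
  b <- seq(0.316, 0.12, length.out = 6)^-2
  e <- powerlaw_exponent(mc_signal(run, b, directions = 60))
  expect_gt(e, 0.45)
  expect_lt(e, 0.65)
})

test_that("configuration invariants are enforced", {
  expect_error(mc_simulate(mc_cylinder(0.3, 100),
                           mc_config(100, sigma = 0.1, duration = 5),
                           data.frame(delta = 1, Delta = 3)),
               "sigma")
  cfg <- mc_config(100, sigma = 0.05, duration = 5)
  expect_error(mc_simulate(mc_cylinder(0.5, 100), cfg,
                           data.frame(delta = 1, Delta = 6)),
               "duration")
  expect_equal(cfg$dt * cfg$n_steps, cfg$duration, tolerance = 1e-12)
})
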