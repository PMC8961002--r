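proto <- exvivo_protocol()

test_that("every model is normalized at b = 0 and decreasing in b", {
  with_b0 <- acq_protocol(c(0, proto$b), c(7.5, proto$Delta),
                          c(4.5, proto$delta))
  models <- list(
    gm_params("SANDI", fe = 0.5, fn = 0.3, fs = 0.18, fim = 0.02,
              De = 0.9, Dn = 2, Rs = 8),
    gm_params("SMEX", fe = 0.54, fn = 0.45, fim = 0.01, De = 0.6, Dn = 1.9,
              tau_n = 8.1),
    gm_params("SANDIX", fe = 0.35, fn = 0.5, fs = 0.14, fim = 0.01,
              De = 0.9, Dn = 0.8, tau_n = 4.5, Rs = 12),
    gm_params("eSANDIX", fe = 0.4, fn = 0.4, fn_imp = 0.03, fs = 0.16,
              fim = 0.01, De = 0.85, Dn = 0.5, tau_n = 4, Rs = 12.5))
  for (p in models) {
    tab <- model_signal(with_b0, p)
    expect_equal(tab$S[tab$b == 0], rep(1, sum(tab$b == 0)), tolerance = 1e-12)
    for (D in unique(tab$Delta)) {
      s <- tab$S[tab$Delta == D]
      expect_true(all(diff(s) < 0))
    }
  }
})

test_that("model nesting reductions hold", {
  # SMEX with infinite residence time equals SANDI without a soma
  pm <- gm_params("SMEX", fe = 0.5, fn = 0.5, De = 1, Dn = 2, tau_n = Inf)
  ps <- gm_params("SANDI", fe = 0.5, fn = 0.5, De = 1, Dn = 2)
  expect_equal(model_signal(proto, pm)$S, model_signal(proto, ps)$S,
               tolerance = 1e-14)
  # eSANDIX with no impermeable sticks equals SANDIX identically
  px <- gm_params("eSANDIX", fe = 0.4, fn = 0.43, fs = 0.16, fim = 0.01,
                  De = 0.85, Dn = 0.5, tau_n = 4, Rs = 12.5)
  py <- gm_params("SANDIX", fe = 0.4, fn = 0.43, fs = 0.16, fim = 0.01,
                  De = 0.85, Dn = 0.5, tau_n = 4, Rs = 12.5)
  expect_identical(model_signal(proto, px)$S, model_signal(proto, py)$S)
})

test_that("parameter validation rejects inconsistent models", {
  expect_error(gm_params("SMEX", fe = 0.5, fn = 0.3, fs = 0.2, De = 1,
                         Dn = 1, tau_n = 5), "soma")
  expect_error(gm_params("SANDIX", fe = 0.5, fn = 0.3, fn_imp = 0.2,
                         De = 1, Dn = 1, tau_n = 5, Rs = 8), "impermeable")
  expect_error(gm_params("SANDI", fe = 0.6, fn = 0.6), "sum to 1")
  expect_error(gm_params("SMEX", fe = 0.5, fn = 0.5, De = 1, Dn = 1,
                         tau_n = -2), "tau_n")
})

test_that("apparent power-law exponent separates sticks from Gaussian decay", {
  b16 <- proto$b[proto$Delta == 16]
  stick <- signal_table(b16, 16, 4.5, stick_powder_signal(b16, 2))
  expect_equal(powerlaw_exponent(stick), 0.5, tolerance = 0.01)
  gauss <- signal_table(b16, 16, 4.5, exp(-b16 * 1))
  expect_gt(powerlaw_exponent(gauss), 1)
  exact <- signal_table(b16, 16, 4.5, 0.2 * b16^(-0.5))
  expect_equal(powerlaw_exponent(exact), 0.5, tolerance = 1e-12)
  expect_error(powerlaw_exponent(stick[stick$b < 2, ]), "4 points")
})

test_that("the time-dependence sign separates exchange from structure", {
  smex <- model_signal(proto, gm_params("SMEX", fe = 0.54, fn = 0.45,
                                        fim = 0.01, De = 0.6, Dn = 1.9,
                                        tau_n = 8.1))
  expect_equal(as.character(time_dependence_sign(smex, b_min = 5)),
               "decreasing")
  sandi <- model_signal(proto, gm_params("SANDI", fe = 0.64, fn = 0.17,
                                         fs = 0.19, De = 0.7, Dn = 2.5,
                                         Rs = 5.4))
  expect_equal(as.character(time_dependence_sign(sandi, b_min = 5)),
               "increasing")
  # a time-independent Gaussian mixture sits inside the dead-band
  flat <- signal_table(rep(c(2, 5, 10), 3), rep(c(7.5, 11, 16), each = 3),
                       4.5, rep(0.5 * exp(-c(2, 5, 10)) +
                                0.5 * exp(-0.3 * c(2, 5, 10)), 3))
  expect_equal(as.character(time_dependence_sign(flat)), "mixed")
})

test_that("powder DKI fit recovers cumulants", {
  b <- seq(0.02, 0.3, length.out = 8)
  gauss <- signal_table(b, 16, 4.5, exp(-1.3 * b))
  fitg <- dki_powder_fit(gauss)
  expect_equal(fitg$D, 1.3, tolerance = 1e-8)
  expect_equal(fitg$K, 0, tolerance = 1e-6)
  # biexponential: D = mean, K = 3 var/mean^2 in the small-b limit
  biexp <- signal_table(b, 16, 4.5, 0.5 * exp(-0.5 * b) + 0.5 * exp(-1.5 * b))
  fitb <- dki_powder_fit(biexp)
  expect_equal(fitb$D, 1.0, tolerance = 0.01)
  expect_equal(fitb$K, 3 * 0.25 / 1, tolerance = 0.05)
})

test_that("Karger-generated DKI shows constant diffusivity and decreasing kurtosis", {
  Deltas <- c(7.5, 11, 16)
  fits <- lapply(Deltas, function(Dl) {
    b <- c(0.1, 0.5, 1, 2, 3)
    S <- vapply(b, function(bb)
      np_powder_oracle(bb, Dl, Dn = 1.35, De = 1.0, fn = 0.55, rn = 1 / 8),
      numeric(1))
    dki_powder_fit(signal_table(b, Dl, 4.5, S))
  })
  D <- vapply(fits, `[[`, numeric(1), "D")
  K <- vapply(fits, `[[`, numeric(1), "K")
  expect_lt(diff(range(D)) / mean(D), 0.02)
  expect_true(all(diff(K) < 0))
})

test_that("signal tables round-trip losslessly at 12 significant digits", {
  tab <- model_signal(proto, gm_params("SMEX", fe = 0.5, fn = 0.5, De = 1,
                                       Dn = 2, tau_n = 10))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_signal_table(tab, f)
  back <- read_signal_table(f)
  expect_equal(back$S, tab$S, tolerance = 1e-11)
  expect_equal(back$b, tab$b, tolerance = 1e-12)
})
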