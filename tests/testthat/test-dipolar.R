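# Rigid-limit couplings, order parameters and the TEDOR buildup model.

test_that("rigid-limit couplings match independent constant evaluation", {
  # frozen from a throwaway evaluation of (mu0/4pi) g1 g2 hbar / (2 pi r^3)
  expect_equal(rigid_limit_coupling(1.10, "CaHa"), 22697.7, tolerance = 1e-4)
  expect_equal(rigid_limit_coupling(1.46, "NCa"), 984.31, tolerance = 1e-4)
  expect_equal(rigid_limit_coupling(1.02, "NH"), 11477.4, tolerance = 1e-4)
  # r^-3 scaling: doubling r divides by exactly 8
  expect_equal(rigid_limit_coupling(2.0, "NH"),
               rigid_limit_coupling(1.0, "NH") / 8)
  expect_error(rigid_limit_coupling(0, "NH"), "domain")
})

test_that("order parameter is the coupling ratio with scaled uncertainty", {
  d <- rigid_limit_coupling(1.10, "CaHa")
  expect_equal(order_parameter(d, d)$S, 1)
  expect_equal(order_parameter(0, d)$S, 0)
  op <- order_parameter(0.98 * d, d, d_err = 0.018 * d)
  expect_equal(op$S, 0.98)
  expect_equal(op$S_err, 0.018)
  expect_error(order_parameter(100, 0), "domain")
})

test_that("tedor signal has the analytic limits and matches the series oracle", {
  expect_equal(tedor_signal(0, 1, 1, 20, 985, 200), 0)      # J0(0) = 1
  tt <- c(0, 1e-3, 5e-3, 1e-2)
  expect_equal(tedor_signal(tt, 2, 0.9, 10, 0, 0), rep(0, 4))
  got <- tedor_signal(2.28e-3, 1, 1, 20, 985, 200)
  expect_equal(got, series_tedor(2.28e-3, 1, 1, 20, 985, 200),
               tolerance = 1e-10)
  # envelope bound |S| <= 2 Lambda(t)
  set.seed(4)
  for (i in 1:50) {
    t <- runif(1, 0, 0.02); d1 <- runif(1, 0, 3000); d2 <- runif(1, 0, 1500)
    g <- runif(1, 0, 50)
    lam_t <- 0.25 * exp(-g * t)
    expect_lte(abs(tedor_signal(t, 1, 1, g, d1, d2)), 2 * lam_t + 1e-12)
  }
})

test_that("tedor fit recovers noiseless parameters to 0.1%", {
  cv <- gen_tedor_curve(D1 = 985, D2 = 150, gamma = 15, noise = 0)
  fit <- fit_tedor(cv)
  expect_equal(fit$D1, 985, tolerance = 1e-3)
  expect_equal(fit$D2, 150, tolerance = 1e-3)
  expect_equal(fit$gamma, 15, tolerance = 1e-3)
  expect_equal(fit$lam, 1, tolerance = 1e-3)
  expect_equal(fit$V0, 1)
})

test_that("tedor fit tolerates 5% noise within 5% on D1", {
  cv <- gen_tedor_curve(D1 = 985, D2 = 150, gamma = 15, noise = 0.05, seed = 0)
  fit <- fit_tedor(cv)
  expect_lt(abs(fit$D1 / 985 - 1), 0.05)
})

test_that("rigid synthetic curve gives S_NCa of 1.000", {
  d_rigid <- rigid_limit_coupling(1.46, "NCa")
  cv <- gen_tedor_curve(D1 = d_rigid, D2 = 150, gamma = 15, noise = 0)
  fit <- fit_tedor(cv)
  expect_equal(fit$order_parameter, 1, tolerance = 1e-3)
})

test_that("degenerate or malformed tedor input errors clearly", {
  z <- data.frame(t_ms = tedor_times_ms(), intensity = 0)
  expect_error(fit_tedor(z), "degenerate")
  short <- data.frame(t_ms = c(1, 2, 3), intensity = c(0.1, 0.2, 0.3))
  expect_error(fit_tedor(short), ">= 6")
})
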