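# Exponential decay fits, the solid spectral density, the 15N rate models
# and the SMF inversion.

test_that("noiseless exponentials are recovered to 4 significant digits", {
  d <- gen_decay_curve(5, M0 = 10, mode = "spinlock", noise = 0)
  f <- fit_spinlock_decay(d, n_mc = 20)
  expect_equal(signif(f$rate, 4), 5)
  expect_equal(f$M0, 10, tolerance = 1e-6)

  d2 <- gen_decay_curve(0.03, M0 = 10, mode = "inversion_recovery", noise = 0)
  f2 <- fit_inversion_recovery(d2, n_mc = 20)
  expect_equal(signif(f2$rate, 4), 0.03)
  # zero-crossing diagnostic of the fitted curve is ln(2)/R1
  expect_equal(f2$t_zero, log(2) / f2$rate)
})

test_that("constant curve fits rate 0 with CI lower bound 0", {
  d <- data.frame(t = spinlock_times_ms() * 1e-3, M = rep(7, 16))
  f <- fit_spinlock_decay(d, n_mc = 20)
  expect_equal(f$rate, 0)
  expect_equal(f$ci95[1], 0)
})

test_that("noisy decays cover the truth and keep the CI reasonable", {
  d <- gen_decay_curve(5, mode = "spinlock", noise = 0.02, seed = 0)
  f <- fit_spinlock_decay(d, seed = 100)
  expect_gte(5, f$ci95[1]); expect_lte(5, f$ci95[2])
  expect_lt(diff(f$ci95), 0.15 * f$rate)
  d2 <- gen_decay_curve(0.03, mode = "inversion_recovery", noise = 0.05,
                        seed = 1)
  f2 <- fit_inversion_recovery(d2, seed = 101)
  expect_gte(0.03, f2$ci95[1]); expect_lte(0.03, f2$ci95[2])
})

test_that("solid spectral density has its analytic limits and integral", {
  expect_equal(spectral_density_solid(c(0, 1e8, 1e9), 1, 50e-9), rep(0, 3))
  expect_equal(spectral_density_solid(0, 0.9, 50e-9), 0.4 * 0.1 * 50e-9)
  # integral over [0, Inf) equals (pi/5)(1 - S2)
  for (s2 in c(0, 0.5, 0.93)) for (tc in c(1e-9, 60e-9, 1e-4)) {
    expect_equal(quad_j_integral(s2, tc), (pi / 5) * (1 - s2),
                 tolerance = 1e-3)
  }
})

test_that("rate models vanish in the rigid limit and match the term oracle", {
  cfg <- spectrometer_config()
  expect_equal(r1_model(1, 60e-9, cfg), 0)
  expect_equal(r1rho_model(1, 60e-9, cfg), 0)
  o <- oracle_rates(0.95, 60e-9)
  expect_equal(r1_model(0.95, 60e-9, cfg), o$r1, tolerance = 1e-10)
  expect_equal(r1rho_model(0.95, 60e-9, cfg), o$r1rho, tolerance = 1e-10)
})

test_that("J(omega_N) contribution peaks at tau_c = 1/omega_N", {
  cfg <- spectrometer_config()
  tau <- exp(seq(log(1e-10), log(1e-7), length.out = 400))
  jn <- spectral_density_solid(cfg$omega_n, 0.9, tau)
  t_star <- tau[which.max(jn)]
  expect_equal(t_star, 1 / cfg$omega_n, tolerance = 0.05)
})

test_that("rate models are nonnegative and R1rho >= R1/2 across the domain", {
  cfg <- spectrometer_config()
  s2 <- seq(0, 1, length.out = 50)
  tau <- exp(seq(log(1e-11), log(1e-2), length.out = 50))
  for (t in tau) {
    r1 <- r1_model(s2, t, cfg)
    rr <- r1rho_model(s2, t, cfg)
    expect_true(all(r1 >= 0) && all(rr >= 0))
    expect_true(all(rr >= r1 / 2 - 1e-12))
  }
})

test_that("SMF inversion recovers both timescale branches", {
  cfg <- spectrometer_config()
  r1 <- r1_model(0.93, 50e-9, cfg); rr <- r1rho_model(0.93, 50e-9, cfg)
  fit <- fit_smf(r1, rr, 0.05 * r1, 0.05 * rr, cfg)
  expect_equal(fit$best$S2, 0.93, tolerance = 0.01)
  expect_equal(fit$best$tau_c, 50e-9, tolerance = 0.12)
  expect_lt(fit$best$chi2, 1e-6)
  expect_identical(fit$best$branch, "fast")
  expect_true(fit$bimodal)   # a slow-branch shadow solution is reported too

  r1s <- r1_model(0.93, 300e-6, cfg); rrs <- r1rho_model(0.93, 300e-6, cfg)
  fits <- fit_smf(r1s, rrs, 0.05 * r1s, 0.05 * rrs, cfg)
  expect_equal(fits$best$tau_c, 300e-6, tolerance = 0.12)
  expect_identical(fits$best$branch, "slow")
})

test_that("zero rates collapse to the rigid branch with tau unidentifiable", {
  fit <- fit_smf(0, 0, 0.001, 0.05)
  expect_equal(fit$best$S2, 1)
  expect_true(fit$tau_unidentifiable)
})
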