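# Wigner matrices, the GAF squared order parameter, frame construction,
# observable prediction and the six-parameter segment fit.

test_that("wigner_d2 has its analytic values and group properties", {
  expect_equal(wigner_d2(0), diag(5))
  expect_equal(wigner_d2(pi / 2)[3, 3], -0.5)      # Legendre P2(0)
  expect_equal(wigner_d2(0.7) %*% wigner_d2(-0.7), diag(5))
})

test_that("gaf_s2 equals the literal quintuple sum and the rigid limit", {
  expect_equal(gaf_s2(c(0.7, 1.2), c(0, 0, 0)), 1, tolerance = 1e-12)
  set.seed(11)
  for (i in 1:10) {
    e <- c(runif(1, 0, pi), runif(1, 0, 2 * pi))
    sig <- runif(3, 0, 25 * pi / 180)
    expect_equal(gaf_s2(e, sig), ref_gaf_s2(e[1], e[2], sig),
                 tolerance = 1e-12)
  }
})

test_that("gaf_s2 matches the Monte-Carlo rotation oracle", {
  sig <- rep(10 * pi / 180, 3)
  e <- c(0.9, 0.5)
  expect_equal(gaf_s2(e, sig), mc_gaf_s2(e[1], e[2], sig, n = 2e5),
               tolerance = 5e-3)
})

test_that("gaf_s2 auto terms are bounded and monotone in each sigma", {
  set.seed(12)
  for (i in 1:200) {
    e <- c(runif(1, 0, pi), runif(1, 0, 2 * pi))
    sig <- runif(3, 0, 25 * pi / 180)
    s2 <- gaf_s2(e, sig)
    expect_gte(s2, 0); expect_lte(s2, 1)
  }
  e <- c(1.1, 0.4)
  for (ax in 1:3) {
    ramp <- seq(0, 25 * pi / 180, length.out = 10)
    vals <- vapply(ramp, function(x) {
      sig <- c(0.1, 0.15, 0.05); sig[ax] <- x
      gaf_s2(e, sig)
    }, numeric(1))
    expect_true(all(diff(vals) <= 1e-10))
  }
})

test_that("relabelling the axes together with their sigmas preserves S2", {
  # exact up to the fixed composition order of the three axis rotations,
  # which contributes < ~1e-3 at sigma <= 25 deg
  tp <- function(v) { v <- v / sqrt(sum(v^2)); c(acos(v[3]), atan2(v[2], v[1])) }
  set.seed(13)
  for (i in 1:20) {
    v <- rnorm(3)
    sig <- runif(3, 0, 25 * pi / 180)
    s0 <- gaf_s2(tp(v), sig)
    s_cyc <- gaf_s2(tp(c(v[2], v[3], v[1])), c(sig[2], sig[3], sig[1]))
    s_swp <- gaf_s2(tp(c(v[2], v[1], v[3])), c(sig[2], sig[1], sig[3]))
    expect_equal(s_cyc, s0, tolerance = 5e-3)
    expect_equal(s_swp, s0, tolerance = 5e-3)
  }
})

test_that("segment frames are orthonormal with gamma along the helix axis", {
  s <- build_ideal_helix(21)
  fr <- suppressWarnings(build_gaf_frames(s, c(2, 21)))
  A <- fr$axes[[1]]
  expect_lt(max(abs(t(A) %*% A - diag(3))), 1e-8)
  # right-handed: alpha x beta = gamma
  ab <- c(A[2, 1] * A[3, 2] - A[3, 1] * A[2, 2],
          A[3, 1] * A[1, 2] - A[1, 1] * A[3, 2],
          A[1, 1] * A[2, 2] - A[2, 1] * A[1, 2])
  expect_equal(unname(ab), unname(A[, 3]), tolerance = 1e-10)
  # gamma is the global helix axis (well within 15 degrees)
  ca <- s$coords$CA[2:21, ]
  ax <- svd(sweep(ca, 2, colMeans(ca)))$v[, 1]
  ang <- acos(min(1, abs(sum(A[, 3] * ax)))) * 180 / pi
  expect_lt(ang, 15)
  # delta = 0 leaves the conventional frame untouched
  fr0 <- suppressWarnings(build_gaf_frames(s, c(2, 21), 0, 0))
  expect_equal(fr0$axes[[1]], A)
})

test_that("predictions have the rigid limit and amplitude-only S_CaHa", {
  cfg <- spectrometer_config()
  s <- build_ideal_helix(21)
  fr <- suppressWarnings(build_gaf_frames(s, c(2, 21)))
  p0 <- predict_observables(gaf_params(c(0, 0, 0), 60e-9), fr, cfg)
  expect_equal(p0$S_CaHa, rep(1, nrow(p0)))
  expect_equal(p0$R1, rep(0, nrow(p0)))
  expect_equal(p0$R1rho, rep(0, nrow(p0)))
  pa <- predict_observables(gaf_params(c(8, 12, 6), 60e-9), fr, cfg)
  pb <- predict_observables(gaf_params(c(8, 12, 6), 120e-9), fr, cfg)
  expect_equal(pa$S_CaHa, pb$S_CaHa)      # tau only enters the rates
  expect_false(isTRUE(all.equal(pa$R1rho, pb$R1rho)))
})

test_that("near-axial ~10 degree rocking lands in the helix rate bands", {
  # qualitative sanity band: helix residues show R1 in [0, 0.05] 1/s and
  # R1rho in [3, 8] 1/s; near-axial rocking (small tilt, ~10 deg about the
  # helix axis) reproduces both
  cfg <- spectrometer_config()
  s <- build_ideal_helix(21)
  fr <- suppressWarnings(build_gaf_frames(s, c(2, 21)))
  p <- predict_observables(gaf_params(c(4, 4, 10), 60e-9), fr, cfg)
  expect_true(all(p$R1 >= 0 & p$R1 <= 0.05))
  expect_true(all(p$R1rho >= 3 & p$R1rho <= 8))
})

test_that("noiseless model data refit to the truth with tiny chi2", {
  cfg <- spectrometer_config()
  gen <- gen_gaf_helix(n_res = 12, noise_s = 0, noise_r = 0, seed = 0)
  # uncertainties for the weights: nominal 2% / 5% levels
  tab <- gen$table
  tab$S_CaHa_err <- 0.02 * tab$S_CaHa
  tab$R1_err <- 0.05 * tab$R1
  tab$R1rho_err <- 0.05 * tab$R1rho
  fit <- suppressWarnings(fit_gaf_segment(tab, gen$structure, c(2, 13), cfg))
  expect_lt(fit$chi2_red, 1e-4)
  expect_equal(fit$params$sigma_deg, c(8, 12, 6), tolerance = 0.05)
  expect_equal(fit$params$tau_c, 60e-9, tolerance = 0.05)
})

test_that("gaf uncertainty intervals shrink to zero width without noise and
          reproduce bit-identically under a seed", {
  cfg <- spectrometer_config()
  gen <- gen_gaf_helix(n_res = 10, noise_s = 0, noise_r = 0, seed = 0)
  tab <- gen$table
  tab$S_CaHa_err <- 1e-8; tab$R1_err <- 1e-8; tab$R1rho_err <- 1e-8
  fit <- suppressWarnings(fit_gaf_segment(tab, gen$structure, c(2, 11), cfg))
  u1 <- gaf_uncertainty(fit, tab, gen$structure, c(2, 11), cfg,
                        n_draws = 8, seed = 5)
  expect_lt(max(u1$upper[1:3] - u1$lower[1:3]), 0.05)   # degrees
  u2 <- gaf_uncertainty(fit, tab, gen$structure, c(2, 11), cfg,
                        n_draws = 8, seed = 5)
  expect_identical(attr(u1, "draws"), attr(u2, "draws"))
})

test_that("degrees of freedom guard rejects undersized segments", {
  cfg <- spectrometer_config()
  gen <- gen_gaf_helix(n_res = 8, seed = 1)
  tab <- gen$table[1:2, ]
  expect_error(suppressWarnings(
    fit_gaf_segment(tab, gen$structure, c(2, 9), cfg)), ">= 3")
})
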