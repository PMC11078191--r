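# Generator contracts: determinism under seeds, attached truth, and
# forward-model consistency.

test_that("generators are pure functions of their seed", {
  a <- gen_tedor_curve(seed = 0); b <- gen_tedor_curve(seed = 0)
  expect_identical(a, b)
  c <- gen_tedor_curve(seed = 1)
  expect_false(isTRUE(all.equal(a$intensity, c$intensity)))
  same <- c("D1", "D2", "gamma", "V0", "lam")   # same truth, different noise
  expect_identical(attr(a, "truth")[same], attr(c, "truth")[same])

  g1 <- gen_gaf_helix(seed = 0); g2 <- gen_gaf_helix(seed = 0)
  expect_identical(g1$table, g2$table)
  t1 <- gen_rocking_trajectory(n_frames = 200, seed = 3)
  t2 <- gen_rocking_trajectory(n_frames = 200, seed = 3)
  expect_identical(t1$coords, t2$coords)
})

test_that("zero-noise curves equal the forward models pointwise", {
  cv <- gen_tedor_curve(D1 = 985, D2 = 150, gamma = 15, noise = 0)
  expect_equal(cv$intensity,
               tedor_signal(cv$t_ms * 1e-3, 1, 1, 15, 985, 150))
  d <- gen_decay_curve(5, M0 = 10, mode = "spinlock", noise = 0)
  expect_equal(d$M, 10 * exp(-5 * d$t))
  # inversion recovery starts at -M0
  ir <- gen_decay_curve(0.03, M0 = 10, mode = "inversion_recovery", noise = 0)
  expect_equal(ir$M[ir$t == 0], -10)
})

test_that("zero-sigma GAF truth gives a rigid table", {
  gen <- gen_gaf_helix(n_res = 8, truth = gaf_params(c(0, 0, 0), 60e-9),
                       noise_s = 0, noise_r = 0, seed = 0)
  expect_equal(gen$table$S_CaHa, rep(1, 8))
  expect_equal(gen$table$R1, rep(0, 8))
  expect_equal(gen$table$R1rho, rep(0, 8))
})

test_that("static rocking trajectory is static with unit DCC", {
  tr <- gen_rocking_trajectory(n_res = 8, rock_sd_deg = 0, atom_noise = 0,
                               n_frames = 150, seed = 0)
  expect_equal(tr$coords[1, , ], tr$coords[150, , ])
  # a strictly static trajectory has zero variance (DCC undefined by
  # convention); rigid-body rocking of any amplitude gives uniformly high
  # correlation (the two rocking axes leave a small geometric residual for
  # atoms close to the pivot)
  D <- dcc_matrix(gen_rocking_trajectory(n_res = 8, rock_sd_deg = 1e-4,
                                         n_frames = 150, seed = 0))
  expect_equal(unname(diag(D)), rep(1, 8))
  expect_true(all(D > 0.85))
})

test_that("water schedules reject overlap and wrong-side starts", {
  bad <- data.frame(molecule = 1, t_start_ns = c(5, 8),
                    duration_ns = c(10, 5), type = c("up", "down"))
  expect_error(gen_water_paths(bad), "overlap")
  wrong <- data.frame(molecule = 1, t_start_ns = c(5, 30),
                      duration_ns = c(10, 5), type = c("up", "up"))
  expect_error(gen_water_paths(wrong), "wrong side")
  none <- data.frame(molecule = 1, t_start_ns = 10, duration_ns = 5,
                     type = "bounce_lo")
  z <- gen_water_paths(none)
  expect_equal(count_permeations(z, -15, 15, 0.1)$events, 0)
})
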