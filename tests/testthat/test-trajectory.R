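# Dynamic cross-correlation, helix angles, permeation counting and
# hydrogen-bond occupancy.

make_traj <- function(coords, resno = seq_len(dim(coords)[2]), dt_ns = 1) {
  gafdyn:::new_trajectory_series(
    coords, data.frame(name = "CA", resno = resno, resname = "ALA",
                       stringsAsFactors = FALSE), dt_ns = dt_ns)
}

test_that("DCC is 1 everywhere for rigid translation and on the diagonal", {
  s <- build_ideal_helix(10)
  X0 <- s$coords$CA
  nf <- 100
  coords <- array(NA_real_, c(nf, 10, 3))
  set.seed(1)
  for (f in 1:nf) coords[f, , ] <- sweep(X0, 2, rnorm(3), "+")
  D <- dcc_matrix(make_traj(coords))
  expect_equal(max(abs(D - 1)), 0, tolerance = 1e-10)
})

test_that("DCC is invariant under a global rotation plus translation", {
  set.seed(2)
  nf <- 300; na <- 8
  coords <- array(rnorm(nf * na * 3), c(nf, na, 3))
  base <- coords
  base[, , 1] <- base[, , 1] + 5 * sin(seq_len(nf) / 10)  # some correlation
  D1 <- dcc_matrix(make_traj(base), window_ns = 100)
  R <- gafdyn:::rotation_about(c(1, 2, 3), 0.8)
  shifted <- base
  for (f in 1:nf) shifted[f, , ] <- base[f, , ] %*% t(R) + rep(c(3, -2, 7), each = na)
  D2 <- dcc_matrix(make_traj(shifted), window_ns = 100)
  expect_equal(D2, D1, tolerance = 1e-10)
})

test_that("independent noise gives near-zero off-diagonal DCC", {
  set.seed(3)
  coords <- array(rnorm(1e4 * 10 * 3), c(1e4, 10, 3))
  D <- dcc_matrix(make_traj(coords))
  expect_lt(mean(abs(D[upper.tri(D)])), 0.05)
  expect_equal(unname(diag(D)), rep(1, 10))
})

test_that("zero-variance atoms are flagged undefined, not propagated", {
  set.seed(4)
  coords <- array(rnorm(200 * 5 * 3), c(200, 5, 3))
  coords[, 3, ] <- 1.5    # frozen atom
  D <- dcc_matrix(make_traj(coords))
  expect_true(all(is.na(D[3, ])))
  expect_true(all(is.finite(D[-3, -3])))
  expect_gt(attr(D, "n_undefined"), 0)
})

test_that("helix angle is zero for identical frames and exact for a
          constructed rotation", {
  s <- build_ideal_helix(12)
  X0 <- s$coords$CA
  ax <- svd(sweep(X0, 2, colMeans(X0)))$v[, 1]
  perp <- gafdyn:::vnorm(gafdyn:::vcross(ax, c(0, 0, 1)))
  R10 <- gafdyn:::rotation_about(perp, 10 * pi / 180)
  coords <- array(NA_real_, c(3, 12, 3))
  coords[1, , ] <- X0
  coords[2, , ] <- X0
  ctr <- colMeans(X0)
  coords[3, , ] <- sweep(sweep(X0, 2, ctr) %*% t(R10), 2, ctr, "+")
  ang <- helix_angle_series(make_traj(coords), c(1, 12))
  expect_equal(ang[1], 0, tolerance = 1e-4)
  expect_equal(ang[2], 0, tolerance = 1e-4)
  expect_equal(ang[3], 10, tolerance = 0.01)
})

test_that("collinear coordinates raise a geometry error", {
  coords <- array(0, c(5, 4, 3))
  for (f in 1:5) coords[f, , 3] <- 1:4        # straight line
  expect_error(helix_angle_series(make_traj(coords), c(1, 4)), "degenerate")
})

test_that("rocking generator angle statistics match the requested amplitude
          and are stationary", {
  tr <- gen_rocking_trajectory(n_res = 20, rock_sd_deg = 10, tau_corr_ns = 50,
                               n_frames = 1e4, seed = 2)
  ang <- helix_angle_series(tr, c(1, 20))
  rms <- attr(ang, "rms_deg")
  expect_lt(abs(rms / 10 - 1), 0.15)
  sd1 <- sd(ang[1:5000]); sd2 <- sd(ang[5001:10000])
  expect_lt(abs(sd1 - sd2) / max(sd1, sd2), 0.2)
})

test_that("permeation counting scores complete crossings only", {
  # monotone crossing
  z <- seq(-20, 20, length.out = 200)
  expect_equal(count_permeations(z, -15, 15)$events, 1)
  # 50 same-side excursions score nothing
  t <- seq(0, 50 * pi, length.out = 5000)
  z2 <- -20 + 18 * abs(sin(t))     # enters from below, exits below
  expect_equal(count_permeations(z2, -15, 15)$events, 0)
})

test_that("a constructed schedule of 7 mixed crossings is counted exactly", {
  sch <- data.frame(
    molecule = c(1, 1, 1, 2, 2, 3, 3, 3, 4, 4),
    t_start_ns = c(5, 30, 60, 10, 50, 8, 35, 70, 20, 55),
    duration_ns = c(8, 8, 8, 6, 6, 5, 10, 5, 7, 7),
    type = c("up", "down", "up", "bounce_lo", "up", "up", "bounce_hi",
             "down", "up", "bounce_hi"))
  z <- gen_water_paths(sch)
  truth <- attr(z, "truth")
  pr <- count_permeations(z, truth$z_lo, truth$z_hi, dt_ns = truth$dt_ns)
  expect_equal(pr$events, 7)
  expect_equal(truth$n_crossings, 7)
  expect_equal(sum(pr$directions == 1), 5)    # five "up" crossings
  expect_equal(sum(pr$directions == -1), 2)
})

test_that("time reversal preserves the count and flips directions", {
  sch <- data.frame(molecule = c(1, 1, 2), t_start_ns = c(10, 50, 30),
                    duration_ns = c(10, 10, 10),
                    type = c("up", "down", "up"))
  z <- gen_water_paths(sch)
  fwd <- count_permeations(z, -15, 15, dt_ns = 0.1)
  rev <- count_permeations(z[nrow(z):1, ], -15, 15, dt_ns = 0.1)
  expect_equal(rev$events, fwd$events)
  expect_equal(sort(rev$directions), sort(-fwd$directions))
})

test_that("permeation rate normalization is per 100 ns", {
  sch <- data.frame(molecule = 1:30, t_start_ns = seq(2, 60, length.out = 30),
                    duration_ns = 5, type = "up")
  z <- gen_water_paths(sch, total_ns = 100, dt_ns = 0.1)
  pr <- count_permeations(z, -15, 15, dt_ns = 0.1)
  expect_equal(pr$events, 30)
  expect_equal(pr$rate_per_100ns, 30, tolerance = 1e-3)
})

test_that("hydrogen-bond occupancy and partner frequency follow geometry", {
  nf <- 120
  donor <- matrix(rep(c(0, 0, 0), each = nf), nf)
  hyd <- matrix(rep(c(1, 0, 0), each = nf), nf)
  aligned <- matrix(rep(c(2.5, 0, 0), each = nf), nf)
  far <- matrix(rep(c(0, 9, 0), each = nf), nf)
  always <- array(c(aligned), c(nf, 1, 3))
  expect_equal(hb_occupancy(donor, hyd, always)$occupancy, 1)
  never <- array(c(far), c(nf, 1, 3))
  hbn <- hb_occupancy(donor, hyd, never)
  expect_equal(hbn$occupancy, 0)
  expect_equal(hbn$n_partners, 0)
  # 3 partners bound in disjoint windows of 40 frames each
  acc <- array(NA_real_, c(nf, 3, 3))
  for (p in 1:3) { acc[, p, 1] <- 0; acc[, p, 2] <- 9; acc[, p, 3] <- 0 }
  for (p in 1:3) {
    w <- ((p - 1) * 40 + 1):(p * 40)
    acc[w, p, 1] <- 2.5; acc[w, p, 2] <- 0; acc[w, p, 3] <- 0
  }
  hb3 <- hb_occupancy(donor, hyd, acc, dt_ns = 1)
  expect_equal(hb3$n_partners, 3)
  expect_equal(hb3$occupancy, 1)              # windows tile all frames
  expect_equal(unname(hb3$per_partner), rep(1 / 3, 3))
  expect_equal(hb3$frequency_per_ns, 3 / nf)
})
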