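# Ground-truth synthetic-data generators. Every generator is a pure
# function of its arguments including the seed, and attaches the generating
# truth to its output so round-trip tests can compare fit against truth
# without the fitters ever seeing it.

#' Generate a synthetic TEDOR buildup curve
#'
#' Forward model [tedor_signal()] evaluated at the mixing-time schedule,
#' plus seeded Gaussian noise with s.d. `noise` times the curve maximum.
#'
#' @param D1,D2 one- and two-bond couplings (Hz).
#' @param gamma transverse decay rate (s^-1).
#' @param V0,lam amplitude and scaling factor.
#' @param times_ms mixing times (ms); default [tedor_times_ms()].
#' @param noise relative noise level (default 0.05).
#' @param seed RNG seed.
#' @return data.frame with `t_ms`, `intensity`, `error` and the generating
#'   parameters in the `"truth"` attribute.
#' @export
gen_tedor_curve <- function(D1 = 985, D2 = 150, gamma = 15, V0 = 1, lam = 1,
                            times_ms = tedor_times_ms(), noise = 0.05,
                            seed = 0) {
  set.seed(seed)
  y0 <- tedor_signal(times_ms * 1e-3, V0, lam, gamma, D1, D2)
  sd <- noise * max(abs(y0))
  y <- y0 + if (sd > 0) stats::rnorm(length(y0), 0, sd) else 0
  out <- data.frame(t_ms = times_ms, intensity = y,
                    error = rep(if (sd > 0) sd else 1e-12, length(y0)))
  attr(out, "truth") <- list(D1 = D1, D2 = D2, gamma = gamma, V0 = V0,
                             lam = lam, noise = noise, seed = seed)
  out
}

#' Generate a synthetic relaxation decay curve
#'
#' Spinlock mode: M(t) = M0 exp(-rate t); inversion-recovery mode:
#' M(t) = M0 (1 - 2 exp(-rate t)) (so M(0) = -M0). Gaussian noise with
#' s.d. `noise * M0` is added.
#'
#' @param rate decay rate (s^-1).
#' @param M0 equilibrium amplitude.
#' @param mode `"spinlock"` or `"inversion_recovery"`.
#' @param times sampling times in s; defaults to the standard schedule of
#'   the chosen mode ([spinlock_times_ms()] / [recovery_times_s()]).
#' @param noise relative noise level.
#' @param seed RNG seed.
#' @return data.frame with `t`, `M`; truth in the `"truth"` attribute.
#' @export
gen_decay_curve <- function(rate, M0 = 10,
                            mode = c("spinlock", "inversion_recovery"),
                            times = NULL, noise = 0.02, seed = 0) {
  mode <- match.arg(mode)
  if (is.null(times))
    times <- if (mode == "spinlock") spinlock_times_ms() * 1e-3 else
      recovery_times_s()
  set.seed(seed)
  y0 <- M0 * .decay_basis(times, rate, mode)
  y <- y0 + if (noise > 0) stats::rnorm(length(y0), 0, noise * abs(M0)) else 0
  out <- data.frame(t = times, M = y)
  attr(out, "truth") <- list(rate = rate, M0 = M0, mode = mode,
                             noise = noise, seed = seed)
  out
}

#' Generate a synthetic helix with GAF-derived observables
#'
#' Builds an ideal alpha-helix (one extra residue so every data residue has
#' a complete peptide-plane frame), computes noiseless {S_CaHa, R1, R1rho}
#' through [predict_observables()] at the true GAF parameters, and adds
#' seeded relative Gaussian noise (defaults: 2% on order parameters, 5% on
#' rates, mirroring typical experimental error-bar magnitudes). The stated
#' noise levels are written into the `_err` columns.
#'
#' @param n_res number of residues with observables (>= 6).
#' @param truth a [gaf_params()]; default sigma = (8, 12, 6) deg,
#'   tau_c = 60 ns.
#' @param noise_s,noise_r relative noise on order parameters / rates.
#' @param cfg a [spectrometer_config()].
#' @param seed RNG seed.
#' @return list with `structure` (a `backbone_structure` of n_res + 1
#'   residues), `table` (measurement table) and `truth`.
#' @export
gen_gaf_helix <- function(n_res = 20,
                          truth = gaf_params(c(8, 12, 6), 60e-9),
                          noise_s = 0.02, noise_r = 0.05,
                          cfg = spectrometer_config(), seed = 0) {
  stopifnot(n_res >= 6)
  # one extra leading residue so every data residue has an amide H
  s <- build_ideal_helix(n_res + 1)
  frames <- suppressWarnings(
    build_gaf_frames(s, c(2, n_res + 1), truth$delta[1], truth$delta[2], cfg))
  pred <- predict_observables(truth, frames, cfg)
  set.seed(seed)
  n <- nrow(pred)
  s_err <- pmax(noise_s * pred$S_CaHa, 1e-6)
  r1_err <- pmax(noise_r * pred$R1, 1e-6)
  r1rho_err <- pmax(noise_r * pred$R1rho, 1e-6)
  tab <- data.frame(
    residue = pred$residue, resname = "ALA", segment = "H1",
    S_CaHa = pred$S_CaHa + if (noise_s > 0) stats::rnorm(n, 0, s_err) else 0,
    S_CaHa_err = s_err,
    R1 = pmax(0, pred$R1 + if (noise_r > 0) stats::rnorm(n, 0, r1_err) else 0),
    R1_err = r1_err,
    R1rho = pmax(0, pred$R1rho +
                   if (noise_r > 0) stats::rnorm(n, 0, r1rho_err) else 0),
    R1rho_err = r1rho_err)
  list(structure = s, table = tab,
       truth = c(truth, list(noise_s = noise_s, noise_r = noise_r,
                             seed = seed)))
}

#' Generate a rigid-helix rocking trajectory
#'
#' A rigid ideal helix is reoriented each frame by two independent
#' Ornstein-Uhlenbeck angle processes about two axes perpendicular to the
#' helix axis (stationary s.d. `rock_sd_deg / sqrt(2)` per axis so the
#' total tilt RMS is `rock_sd_deg`; correlation time `tau_corr_ns`),
#' starting from the mean orientation, plus independent per-atom Gaussian
#' jitter. The rocking pivots 5 Angstrom below the helix N-terminal end,
#' emulating a transmembrane helix anchored by its connecting loop, so all
#' residues of the helix move in concert. This is the minimal stationary single-timescale model
#' of small-amplitude collective helix rocking.
#'
#' @param n_res helix length in residues.
#' @param rock_sd_deg total tilt RMS amplitude in degrees.
#' @param tau_corr_ns correlation time of the rocking (ns).
#' @param dt_ns time per frame (ns).
#' @param n_frames number of frames (>= 100).
#' @param atom_noise s.d. of independent per-atom jitter (Angstrom).
#' @param seed RNG seed.
#' @return a `trajectory_series` (Ca atoms only) with the generating truth
#'   in the `"truth"` attribute.
#' @export
gen_rocking_trajectory <- function(n_res = 20, rock_sd_deg = 10,
                                   tau_corr_ns = 50, dt_ns = 1,
                                   n_frames = 2000, atom_noise = 0,
                                   seed = 0) {
  stopifnot(n_frames >= 100)
  s <- build_ideal_helix(n_res)
  X0 <- s$coords$CA
  sv <- svd(sweep(X0, 2, colMeans(X0)))
  ax <- sv$v[, 1]                      # helix axis
  if (sum(ax * (X0[n_res, ] - X0[1, ])) < 0) ax <- -ax
  p1 <- sv$v[, 2]; p2 <- sv$v[, 3]     # perpendicular rocking axes
  ctr <- X0[1, ] - 5 * ax              # pivot in the anchoring loop region
  Xc <- sweep(X0, 2, ctr)
  set.seed(seed)
  sd_axis <- (rock_sd_deg * pi / 180) / sqrt(2)
  rho <- exp(-dt_ns / tau_corr_ns)
  innov_sd <- sd_axis * sqrt(1 - rho^2)
  th1 <- th2 <- numeric(n_frames)
  for (f in 2:n_frames) {
    th1[f] <- rho * th1[f - 1] + stats::rnorm(1, 0, innov_sd)
    th2[f] <- rho * th2[f - 1] + stats::rnorm(1, 0, innov_sd)
  }
  coords <- array(NA_real_, c(n_frames, n_res, 3))
  for (f in seq_len(n_frames)) {
    R <- rotation_about(p1, th1[f]) %*% rotation_about(p2, th2[f])
    Xf <- Xc %*% t(R)
    if (atom_noise > 0)
      Xf <- Xf + matrix(stats::rnorm(length(Xf), 0, atom_noise), nrow = n_res)
    coords[f, , ] <- sweep(Xf, 2, ctr, "+")
  }
  atoms <- data.frame(name = "CA", resno = seq_len(n_res), resname = "ALA",
                      stringsAsFactors = FALSE)
  traj <- new_trajectory_series(coords, atoms, dt_ns = dt_ns)
  attr(traj, "truth") <- list(rock_sd_deg = rock_sd_deg,
                              tau_corr_ns = tau_corr_ns,
                              atom_noise = atom_noise, seed = seed)
  traj
}

#' Generate per-molecule water z-paths with a known crossing schedule
#'
#' Builds piecewise-smooth z(t) series realizing exactly the scheduled full
#' crossings and same-side excursions, for round-trip tests of
#' [count_permeations()].
#'
#' @param schedule data.frame with columns `molecule` (integer),
#'   `t_start_ns`, `duration_ns` and `type` (`"up"` = full -z to +z
#'   crossing, `"down"` = full +z to -z crossing, `"bounce_lo"`,
#'   `"bounce_hi"` = same-side excursions into the slab and back).
#'   Segments of one molecule must not overlap.
#' @param z_lo,z_hi slab boundaries (default -15, 15 Angstrom).
#' @param margin how far outside the slab the paths rest (default 5).
#' @param dt_ns time per frame.
#' @param total_ns total trajectory length.
#' @return matrix (frames x molecules) of z coordinates with the schedule
#'   and expected crossing count in the `"truth"` attribute.
#' @export
gen_water_paths <- function(schedule, z_lo = -15, z_hi = 15, margin = 5,
                            dt_ns = 0.1, total_ns = 100) {
  nf <- round(total_ns / dt_ns) + 1
  tt <- (seq_len(nf) - 1) * dt_ns
  mols <- sort(unique(schedule$molecule))
  z <- matrix(NA_real_, nf, length(mols))
  for (mi in seq_along(mols)) {
    seg <- schedule[schedule$molecule == mols[mi], , drop = FALSE]
    seg <- seg[order(seg$t_start_ns), , drop = FALSE]
    if (nrow(seg) > 1 &&
        any(seg$t_start_ns[-1] < (seg$t_start_ns + seg$duration_ns)[-nrow(seg)]))
      stop("spec error: overlapping schedule segments for molecule ", mols[mi])
    # resting side before the first segment
    side <- if (nrow(seg) > 0 && seg$type[1] %in% c("down", "bounce_hi"))
      "hi" else "lo"
    zm <- rep(if (side == "lo") z_lo - margin else z_hi + margin, nf)
    for (k in seq_len(nrow(seg))) {
      t0 <- seg$t_start_ns[k]; t1 <- t0 + seg$duration_ns[k]
      ok <- switch(seg$type[k],
        up = , bounce_lo = side == "lo",
        down = , bounce_hi = side == "hi",
        stop("spec error: unknown segment type ", seg$type[k]))
      if (!ok)
        stop("spec error: segment ", k, " of molecule ", mols[mi],
             " starts from the wrong side")
      inseg <- tt >= t0 & tt <= t1
      u <- (tt[inseg] - t0) / (t1 - t0)          # 0..1 progress
      zm[inseg] <- switch(seg$type[k],
        up = z_lo - margin + (z_hi + margin - (z_lo - margin)) *
          (1 - cos(pi * u)) / 2,
        down = z_hi + margin - (z_hi + margin - (z_lo - margin)) *
          (1 - cos(pi * u)) / 2,
        bounce_lo = z_lo - margin +
          ((z_lo + z_hi) / 2 - (z_lo - margin)) * sin(pi * u),
        bounce_hi = z_hi + margin -
          ((z_hi + margin) - (z_lo + z_hi) / 2) * sin(pi * u),
        stop("spec error: unknown segment type ", seg$type[k]))
      side <- switch(seg$type[k], up = "hi", down = "lo", side)
      zm[tt > t1] <- if (side == "lo") z_lo - margin else z_hi + margin
    }
    z[, mi] <- zm
  }
  colnames(z) <- mols
  n_cross <- sum(schedule$type %in% c("up", "down"))
  attr(z, "truth") <- list(schedule = schedule, n_crossings = n_cross,
                           z_lo = z_lo, z_hi = z_hi, dt_ns = dt_ns,
                           total_ns = total_ns)
  z
}
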