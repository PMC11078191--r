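# The 3D Gaussian axial fluctuation (GAF) engine: second-rank Wigner
# matrices, the closed-form squared order parameter for Gaussian rigid-body
# rocking about three orthogonal axes, peptide-plane frame construction,
# observable prediction, and the six-parameter reduced-chi-square fit.

#' Second-rank reduced Wigner matrix
#'
#' d^2_kl(beta) for k, l in -2..2 (rows k, columns l), from the general
#' factorial formula.
#'
#' @param beta rotation angle in radians.
#' @return a 5 x 5 numeric matrix.
#' @export
wigner_d2 <- function(beta) {
  j <- 2
  ms <- -2:2
  d <- matrix(0, 5, 5)
  cb <- cos(beta / 2); sb <- sin(beta / 2)
  for (a in 1:5) for (b in 1:5) {
    mp <- ms[a]; m <- ms[b]
    s <- max(0, m - mp):min(j + m, j - mp)
    pref <- sqrt(factorial(j + mp) * factorial(j - mp) *
                 factorial(j + m) * factorial(j - m))
    d[a, b] <- pref * sum((-1)^(mp - m + s) *
      cb^(2 * j + m - mp - 2 * s) * sb^(mp - m + 2 * s) /
      (factorial(j + m - s) * factorial(s) * factorial(mp - m + s) *
       factorial(j - mp - s)))
  }
  d
}

# complex spherical harmonics Y_2m(theta, phi), m = -2..2
.y2 <- function(theta, phi) {
  st <- sin(theta); ct <- cos(theta)
  c(sqrt(15 / (32 * pi)) * st^2 * exp(-2i * phi),
    sqrt(15 / (8 * pi)) * st * ct * exp(-1i * phi),
    sqrt(5 / (16 * pi)) * (3 * ct^2 - 1),
    -sqrt(15 / (8 * pi)) * st * ct * exp(1i * phi),
    sqrt(15 / (32 * pi)) * st^2 * exp(2i * phi))
}

.d2_halfpi <- wigner_d2(pi / 2)

# 5 x 5 complex kernel M(sigma) such that
#   S2_{mu nu} = Re( t(y_mu) %*% M %*% Conj(y_nu) )
# collapsing the quintuple sum over (l, k, k', m, m') of the GAF order
# parameter into nested matrix products; reused across bond vectors.
gaf_kernel <- function(sigma) {
  d <- .d2_halfpi
  ms <- -2:2
  eb <- exp(-sigma[2]^2 * ms^2)
  B <- d %*% (eb * t(d))                      # sum over l
  ea <- exp(-sigma[1]^2 * ms^2 / 2)
  phase <- outer(ms, ms, function(k, kp) (-1i)^(k - kp))
  A <- phase * outer(ea, ea) * B              # k, k' damping and phase
  C <- d %*% A %*% t(d)                       # to m, m'
  eg <- exp(-sigma[3]^2 * ms^2 / 2)
  (4 * pi / 5) * outer(eg, eg) * C
}

#' GAF squared order parameter
#'
#' Closed-form squared order parameter of rank-2 interactions under
#' Gaussian rigid-body fluctuations of amplitude (sigma_alpha, sigma_beta,
#' sigma_gamma) radians about the three orthogonal frame axes. The bond
#' vectors are given as spherical coordinates (theta from the gamma axis,
#' phi from the alpha axis) in the fluctuation frame. For an
#' auto-correlation term (mu = nu) the result is real and lies in \[0, 1\];
#' sigma = 0 gives exactly 1.
#'
#' @param e_mu,e_nu numeric length-2 vectors `c(theta, phi)` (radians);
#'   `e_nu` defaults to `e_mu` (auto term).
#' @param sigma length-3 fluctuation amplitudes (radians), all >= 0.
#' @return the squared order parameter (real part).
#' @export
gaf_s2 <- function(e_mu, sigma, e_nu = e_mu) {
  stopifnot(length(sigma) == 3, all(sigma >= 0))
  M <- gaf_kernel(sigma)
  y_mu <- .y2(e_mu[1], e_mu[2])
  y_nu <- .y2(e_nu[1], e_nu[2])
  Re(sum(y_mu * (M %*% Conj(y_nu))))
}

#' GAF model parameters
#'
#' @param sigma_deg length-3 fluctuation amplitudes about the (alpha, beta,
#'   gamma) axes, degrees.
#' @param tau_c effective correlation time, seconds.
#' @param delta_deg length-2 frame-adjustment angles (delta_theta,
#'   delta_phi), degrees: a polar reorientation of the fluctuation axes
#'   relative to the geometric peptide-plane convention.
#' @return object of class `gaf_params` with `sigma` and `delta` in radians.
#' @export
gaf_params <- function(sigma_deg, tau_c, delta_deg = c(0, 0)) {
  stopifnot(length(sigma_deg) == 3, all(sigma_deg >= 0),
            all(sigma_deg <= 45), tau_c > 0, length(delta_deg) == 2)
  structure(list(sigma = sigma_deg * pi / 180, tau_c = tau_c,
                 delta = delta_deg * pi / 180,
                 sigma_deg = sigma_deg, delta_deg = delta_deg),
            class = "gaf_params")
}

#' @export
print.gaf_params <- function(x, ...) {
  cat(sprintf(
    "gaf_params: sigma = (%.1f, %.1f, %.1f) deg, tau_c = %.3g s, delta = (%.1f, %.1f) deg\n",
    x$sigma_deg[1], x$sigma_deg[2], x$sigma_deg[3], x$tau_c,
    x$delta_deg[1], x$delta_deg[2]))
  invisible(x)
}

#' Build the segment GAF frame and per-residue interaction vectors
#'
#' The collective motion is rigid-body rocking of the whole segment, so one
#' axis triad serves every residue: the gamma axis is the helix principal
#' axis (leading singular vector of the centered segment Ca coordinates,
#' oriented toward increasing residue number); beta is seeded from the
#' first residue's radial direction (Ca minus its axial projection),
#' orthogonalized against gamma; alpha completes a right-handed triad
#' (alpha x beta = gamma). The triad is then tilted by the polar
#' reorientation (delta_theta toward the in-plane azimuth delta_phi), the
#' two frame angles fitted because the true fluctuation axes are not known
#' a priori. The N-H, Ca-Ha and N-Ca bond vectors and the 15N CSA symmetry
#' axis (N-H tilted by `cfg$csa_tilt_deg` about the local amide-plane
#' normal) of every residue are expressed as (theta, phi) in this frame.
#'
#' @param s a `backbone_structure`.
#' @param segment residue range: numeric `c(first, last)` or a
#'   [segment_definition()] row. Needs >= 4 residues with Ca.
#' @param delta_theta,delta_phi frame-adjustment angles in radians.
#' @param cfg a [spectrometer_config()] (for the CSA tilt).
#' @return list with `resno`, `axes` (list of 3x3 matrices, columns alpha,
#'   beta, gamma; identical across residues) and `vectors` (data.frame
#'   residue, kind, theta, phi).
#' @export
build_gaf_frames <- function(s, segment, delta_theta = 0, delta_phi = 0,
                             cfg = spectrometer_config()) {
  rng <- if (is.data.frame(segment))
    c(segment$first_residue[1], segment$last_residue[1]) else segment
  res <- s$resno[s$resno >= rng[1] & s$resno <= rng[2]]
  if (length(res) == 0) stop("segment contains no residue of the structure")
  idx <- match(res, s$resno)
  CA <- s$coords$CA[idx, , drop = FALSE]
  okca <- !is.na(CA[, 1])
  if (sum(okca) < 4) stop("segment needs >= 4 residues with Ca coordinates")
  Xc <- sweep(CA[okca, , drop = FALSE], 2, colMeans(CA[okca, , drop = FALSE]))
  sv <- svd(Xc)
  gam <- sv$v[, 1]
  if (sum(gam * (Xc[nrow(Xc), ] - Xc[1, ])) < 0) gam <- -gam
  radial <- Xc[1, ] - sum(Xc[1, ] * gam) * gam
  bet <- vnorm(radial)
  alp <- vcross(bet, gam)                   # alpha x beta = gamma
  if (delta_theta != 0) {
    u <- cos(delta_phi) * alp + sin(delta_phi) * bet
    R <- rotation_about(u, delta_theta)
    alp <- as.vector(R %*% alp); bet <- as.vector(R %*% bet)
    gam <- as.vector(R %*% gam)
  }
  A <- cbind(alpha = alp, beta = bet, gamma = gam)

  tilt <- cfg$csa_tilt_deg * pi / 180
  axes <- list(); vecs <- list(); kept <- integer(0); skipped <- integer(0)
  for (r in res) {
    i <- match(r, s$resno)
    CA1 <- s$coords$CA[i, ]
    if (is.na(CA1[1])) { skipped <- c(skipped, r); next }
    Ni <- s$coords$N[i, ]; Hi <- s$coords$H[i, ]; HAi <- s$coords$HA[i, ]
    vlist <- list()
    if (!anyNA(c(Ni, Hi))) {
      v_nh <- Hi - Ni
      vlist$NH <- v_nh
      # CSA symmetry axis: N-H tilted in the amide plane; the plane normal
      # comes from the preceding peptide plane when available, else beta
      k <- match(r - 1, s$resno)
      n_pl <- if (!is.na(k) && !anyNA(c(s$coords$C[k, ], s$coords$O[k, ])))
        vnorm(vcross(s$coords$O[k, ] - s$coords$C[k, ], Ni - s$coords$C[k, ]))
      else bet
      vlist$CSA <- as.vector(rotation_about(n_pl, tilt) %*% vnorm(v_nh))
    }
    if (!anyNA(c(CA1, HAi))) vlist$CaHa <- HAi - CA1
    if (!anyNA(c(Ni, CA1))) vlist$NCa <- CA1 - Ni
    if (length(vlist) == 0) { skipped <- c(skipped, r); next }
    for (kind in names(vlist)) {
      tp <- frame_polar(vlist[[kind]], alp, bet, gam)
      vecs[[length(vecs) + 1]] <- data.frame(
        residue = r, kind = kind, theta = tp[["theta"]], phi = tp[["phi"]])
    }
    axes[[as.character(r)]] <- A
    kept <- c(kept, r)
  }
  if (length(skipped))
    warning("residue(s) without usable geometry excluded: ",
            paste(skipped, collapse = ", "))
  if (length(kept) == 0) stop("no residue with usable geometry")
  list(resno = kept, axes = axes, vectors = do.call(rbind, vecs))
}

#' Predict ssNMR observables from GAF parameters
#'
#' For each residue with frames: S_CaHa is the square root of the GAF
#' auto squared order parameter of the Ca-Ha vector; R1 and R1rho come from
#' the relaxation rate models with the squared order parameter of each
#' interaction (N-H dipole for the dipolar terms, CSA axis for the CSA
#' terms) substituted into its own spectral density. Amplitudes alone set
#' S_CaHa; the timescale only enters the rates.
#'
#' @param params a [gaf_params()] (its `delta` is not re-applied here; build
#'   the frames with the intended delta).
#' @param frames result of [build_gaf_frames()].
#' @param cfg a [spectrometer_config()].
#' @return data.frame with residue, S_CaHa, R1, R1rho.
#' @export
predict_observables <- function(params, frames, cfg = spectrometer_config()) {
  M <- gaf_kernel(params$sigma)
  a <- rate_coefficients(params$tau_c, cfg)
  out <- lapply(frames$resno, function(r) {
    v <- frames$vectors[frames$vectors$residue == r, ]
    s2_of <- function(kind) {
      row <- v[v$kind == kind, ]
      if (nrow(row) == 0) return(NA_real_)
      y <- .y2(row$theta, row$phi)
      Re(sum(y * (M %*% Conj(y))))
    }
    s2ca <- s2_of("CaHa"); s2nh <- s2_of("NH"); s2csa <- s2_of("CSA")
    if (anyNA(c(s2ca, s2nh, s2csa))) return(NULL)  # skipped, logged below
    data.frame(residue = r,
               S_CaHa = sqrt(max(0, s2ca)),
               R1 = (1 - s2nh) * a$r1_dip + (1 - s2csa) * a$r1_csa,
               R1rho = (1 - s2nh) * a$r1rho_dip + (1 - s2csa) * a$r1rho_csa)
  })
  dropped <- frames$resno[vapply(out, is.null, logical(1))]
  if (length(dropped))
    message("residue(s) missing an interaction vector skipped: ",
            paste(dropped, collapse = ", "))
  do.call(rbind, out)
}
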