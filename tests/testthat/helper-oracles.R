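# Independent oracles used to freeze expected values. Each one evaluates
# the physics by a different route than the package (literal sums, series
# expansions, Monte-Carlo sampling, quadrature) so agreement is evidence,
# not tautology.

# --- Monte-Carlo rotational-sampling oracle for the GAF order parameter ---
# Samples Gaussian rotation angles about the three frame axes, applies the
# composition R_beta(b) R_alpha(a) R_gamma(g) to the bond vector, and
# averages the rank-2 spherical harmonics. Vectorized over samples.
mc_gaf_s2 <- function(theta, phi, sigma, n = 2e5, seed = 1) {
  set.seed(seed)
  a <- rnorm(n, 0, sigma[1]); b <- rnorm(n, 0, sigma[2])
  g <- rnorm(n, 0, sigma[3])
  x <- sin(theta) * cos(phi); y <- sin(theta) * sin(phi); z <- cos(theta)
  # about z (gamma)
  x1 <- x * cos(g) - y * sin(g); y1 <- x * sin(g) + y * cos(g); z1 <- z
  # about x (alpha)
  x2 <- x1; y2 <- y1 * cos(a) - z1 * sin(a); z2 <- y1 * sin(a) + z1 * cos(a)
  # about y (beta)
  x3 <- x2 * cos(b) + z2 * sin(b); y3 <- y2; z3 <- -x2 * sin(b) + z2 * cos(b)
  ct <- pmin(1, pmax(-1, z3)); st <- sqrt(pmax(0, 1 - ct^2))
  ph <- atan2(y3, x3)
  ym <- c(mean(sqrt(15 / (32 * pi)) * st^2 * exp(-2i * ph)),
          mean(sqrt(15 / (8 * pi)) * st * ct * exp(-1i * ph)),
          mean(sqrt(5 / (16 * pi)) * (3 * ct^2 - 1)),
          mean(-sqrt(15 / (8 * pi)) * st * ct * exp(1i * ph)),
          mean(sqrt(15 / (32 * pi)) * st^2 * exp(2i * ph)))
  Re((4 * pi / 5) * sum(ym * Conj(ym)))
}

# --- literal quintuple-sum reference for the GAF order parameter ---
# Direct transcription of the five nested sums, no matrix reshaping.
ref_gaf_s2 <- function(theta, phi, sigma) {
  d <- wigner_d2(pi / 2)
  y <- c(sqrt(15 / (32 * pi)) * sin(theta)^2 * exp(-2i * phi),
         sqrt(15 / (8 * pi)) * sin(theta) * cos(theta) * exp(-1i * phi),
         sqrt(5 / (16 * pi)) * (3 * cos(theta)^2 - 1),
         -sqrt(15 / (8 * pi)) * sin(theta) * cos(theta) * exp(1i * phi),
         sqrt(15 / (32 * pi)) * sin(theta)^2 * exp(2i * phi))
  tot <- 0 + 0i
  for (l in -2:2) for (k in -2:2) for (kp in -2:2)
    for (m in -2:2) for (mp in -2:2) {
      tot <- tot + (-1i)^(k - kp) *
        exp(-sigma[1]^2 * (k^2 + kp^2) / 2 - sigma[2]^2 * l^2 -
            sigma[3]^2 * (m^2 + mp^2) / 2) *
        d[k + 3, l + 3] * d[kp + 3, l + 3] * d[m + 3, k + 3] *
        d[mp + 3, kp + 3] * y[m + 3] * Conj(y[mp + 3])
    }
  Re((4 * pi / 5) * tot)
}

# --- power-series Bessel oracle for the TEDOR signal ---
# J0 from its power series (40 terms), assembled into the buildup formula
# without calling besselJ.
series_tedor <- function(t_mix, V0, lam, gamma, D1, D2, n_coupled = 2) {
  j0 <- function(x) {
    k <- 0:40
    sum((-1)^k * (x / 2)^(2 * k) / factorial(k)^2)
  }
  lam_t <- (1 / 2^n_coupled) * V0 * lam * exp(-gamma * t_mix)
  lam_t * (1 - j0(sqrt(2) * D1 * t_mix)^2) * (1 + j0(sqrt(2) * D2 * t_mix)^2)
}

# --- term-by-term relaxation-rate oracle ---
# Independent spelled-out evaluation of the R1 / R1rho expressions with its
# own constants, bypassing rate_coefficients().
oracle_rates <- function(S2, tau_c, proton_mhz = 800, mas_khz = 40,
                         spinlock_khz = 10, delta_csa_ppm = -170,
                         r_nh = 1.02) {
  gH <- 2.6752218744e8; gN <- 2.71261804e7
  wh <- 2 * pi * proton_mhz * 1e6
  wn <- wh * gN / gH
  w1 <- 2 * pi * spinlock_khz * 1e3
  wr <- 2 * pi * mas_khz * 1e3
  dnh <- 1e-7 * gH * gN * 1.054571817e-34 / (r_nh * 1e-10)^3  # rad/s
  dcsa <- delta_csa_ppm * 1e-6
  J <- function(w) (2 / 5) * (1 - S2) * tau_c / (1 + (w * tau_c)^2)
  r1_csa <- (3 / 4) * (dcsa * wn)^2 * J(wn)
  r1_nh <- (dnh^2 / 4) * (J(wh - wn) + 3 * J(wn) + 6 * J(wh + wn))
  r1 <- r1_csa + r1_nh
  side <- (1 / 3) * J(w1 - 2 * wr) + (2 / 3) * J(w1 - wr) +
    (2 / 3) * J(w1 + wr) + (1 / 3) * J(w1 + 2 * wr)
  r1rho <- 0.5 * r1 + ((dcsa * wn)^2 / 4) * side +
    (dnh^2 / 4) * (3 * J(wh) + side)
  list(r1 = r1, r1rho = r1rho)
}

# numeric quadrature of the solid spectral density over [0, Inf); the
# frequency axis is rescaled by tau_c so the quadrature sees an O(1) width
quad_j_integral <- function(S2, tau_c) {
  stats::integrate(function(u) spectral_density_solid(u / tau_c, S2, tau_c) /
                     tau_c, 0, Inf, rel.tol = 1e-10)$value
}
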