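# Small 3-vector helpers shared by the structure and trajectory code.

vnorm <- function(v) {
  n <- sqrt(sum(v * v))
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rodrigues rotation matrix: angle in radians about unit axis
rotation_about <- function(axis, angle) {
  u <- vnorm(axis)
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Natural extension reference frame: place atom D bonded to C, given A-B-C,
# with bond length |CD|, angle B-C-D and torsion A-B-C-D (radians).
nerf_place <- function(a, b, c, bond, angle, torsion) {
  bc <- vnorm(c - b)
  n <- vnorm(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- bond * c(-cos(angle), sin(angle) * cos(torsion), sin(angle) * sin(torsion))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# polar coordinates of vector v in the orthonormal frame (x=alpha, y=beta,
# z=gamma); returns c(theta, phi) with theta in [0,pi], phi in [0,2pi)
frame_polar <- function(v, alpha, beta, gamma) {
  u <- vnorm(v)
  x <- sum(u * alpha); y <- sum(u * beta); z <- sum(u * gamma)
  theta <- acos(min(1, max(-1, z)))
  phi <- atan2(y, x)
  if (phi < 0) phi <- phi + 2 * pi
  c(theta = theta, phi = phi)
}
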