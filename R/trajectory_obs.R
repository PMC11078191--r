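# Trajectory-derived collective-motion observables: windowed dynamic
# cross-correlation, helix orientation fluctuation, water permeation
# counting, and hydrogen-bond occupancy/frequency.

#' Dynamic cross-correlation matrix
#'
#' Normalized covariance of positional fluctuations between residue pairs:
#' within each non-overlapping window the per-atom mean position is removed,
#' DCC_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2|>), and the returned
#' matrix is the average over windows. Values near 1 indicate same-direction
#' collective motion, near 0 independent motion. Atoms with zero variance in
#' a window get NA entries (flagged, not propagated into other pairs).
#'
#' @param traj a `trajectory_series`.
#' @param window_ns window length in ns (default: the whole trajectory as a
#'   single window).
#' @param selection atom filter (list with `elety` and/or `resno`) picking
#'   one atom per residue; default Ca atoms when present.
#' @return matrix of class `dcc_matrix` (residues x residues) with the
#'   window length in the `"window_ns"` attribute and the count of
#'   undefined entries in `"n_undefined"`.
#' @export
dcc_matrix <- function(traj, window_ns = NULL, selection = list(elety = "CA")) {
  atoms <- traj$atoms
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(selection$elety) && any(atoms$name %in% selection$elety))
    keep <- keep & atoms$name %in% selection$elety
  if (!is.null(selection$resno)) keep <- keep & atoms$resno %in% selection$resno
  if (!any(keep)) stop("empty selection: no atom matches")
  X <- traj$coords[, keep, , drop = FALSE]
  nf <- dim(X)[1]; na <- dim(X)[2]
  .check_pbc(traj, X)
  wlen <- if (is.null(window_ns)) nf else max(2L, round(window_ns / traj$dt_ns))
  if (wlen < 2) stop("window must span >= 2 frames")
  nw <- nf %/% wlen
  if (nw < 1) stop("window longer than the trajectory")
  acc <- matrix(0, na, na); cnt <- matrix(0, na, na)
  for (w in seq_len(nw)) {
    rows <- ((w - 1) * wlen + 1):(w * wlen)
    C <- matrix(0, na, na)
    for (k in 1:3) {
      Xk <- X[rows, , k, drop = FALSE][, , 1]
      Xk <- sweep(Xk, 2, colMeans(Xk))
      C <- C + crossprod(Xk)
    }
    v <- diag(C)
    ok <- v > 0
    denom <- sqrt(outer(v, v))
    Cw <- matrix(NA_real_, na, na)
    Cw[ok, ok] <- C[ok, ok] / denom[ok, ok]
    def <- !is.na(Cw)
    acc[def] <- acc[def] + Cw[def]
    cnt <- cnt + def
  }
  out <- ifelse(cnt > 0, acc / cnt, NA_real_)
  rownames(out) <- colnames(out) <- atoms$resno[keep]
  attr(out, "window_ns") <- wlen * traj$dt_ns
  attr(out, "n_undefined") <- sum(cnt == 0)
  class(out) <- c("dcc_matrix", class(out))
  out
}

# guard against wrapped periodic coordinates: reject jumps beyond half the
# declared box (synthetic fixtures are unwrapped, so this only fires on
# genuinely wrapped input)
.check_pbc <- function(traj, X) {
  if (is.null(traj$box)) return(invisible())
  d <- apply(abs(X[-1, , , drop = FALSE] - X[-dim(X)[1], , , drop = FALSE]),
             3, max)
  if (any(d > traj$box / 2))
    stop("frame-to-frame displacement exceeds half the declared box; ",
         "unwrap the trajectory first")
  invisible()
}

#' Helix orientation fluctuation
#'
#' The helix axis of each frame is the principal direction of the segment's
#' Ca coordinates (sign-fixed by continuity to the frame-0 axis); the
#' reported angle is the arccos of its dot product with the frame-0 axis,
#' in degrees. The RMS of this series measures the rocking amplitude about
#' the reference orientation.
#'
#' @param traj a `trajectory_series`.
#' @param segment residue range `c(first, last)` or [segment_definition()]
#'   row; needs >= 4 Ca atoms.
#' @return numeric vector of angles (degrees), one per frame, with the RMS
#'   in the `"rms_deg"` attribute.
#' @export
helix_angle_series <- function(traj, segment) {
  rng <- if (is.data.frame(segment))
    c(segment$first_residue[1], segment$last_residue[1]) else segment
  keep <- traj$atoms$name == "CA" & traj$atoms$resno >= rng[1] &
    traj$atoms$resno <= rng[2]
  if (sum(keep) < 4) stop("segment needs >= 4 Ca atoms")
  X <- traj$coords[, keep, , drop = FALSE]
  nf <- dim(X)[1]
  axis_of <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    sv <- svd(m, nu = 0, nv = 3)
    # a helix spreads over >= 2 directions; a point set that is (near-)
    # collinear or fully degenerate has no stable axis convention here
    if (sv$d[1] < 1e-8 || sv$d[2] < 1e-6 * sv$d[1])
      stop("geometry error: degenerate (collinear) coordinates")
    sv$v[, 1]
  }
  a0 <- axis_of(X[1, , ])
  # orient the reference along increasing residue number
  ca1 <- X[1, , ]
  if (sum(a0 * (ca1[nrow(ca1), ] - ca1[1, ])) < 0) a0 <- -a0
  ang <- numeric(nf)
  prev <- a0
  for (f in seq_len(nf)) {
    a <- axis_of(X[f, , ])
    if (sum(a * prev) < 0) a <- -a       # continuity, avoids 180-deg flips
    ang[f] <- acos(min(1, max(-1, sum(a * a0)))) * 180 / pi
    prev <- a
  }
  attr(ang, "rms_deg") <- sqrt(mean(ang^2))
  ang
}

#' Count water permeation events
#'
#' A permeation event is a complete crossing of the membrane slab: a
#' molecule enters the slab through one boundary and next leaves through the
#' other. Re-exits through the entry side score nothing.
#'
#' @param z matrix of z coordinates (frames x molecules, Angstrom) or a
#'   vector for a single molecule.
#' @param z_lo,z_hi slab boundaries (z_lo < z_hi).
#' @param dt_ns time per frame in ns (default 1).
#' @return object of class `permeation_record`: `events` (count),
#'   `event_times` (ns), `directions` (+1 for -z to +z, -1 otherwise) and
#'   `rate_per_100ns`.
#' @export
count_permeations <- function(z, z_lo, z_hi, dt_ns = 1) {
  if (z_lo >= z_hi) stop("z_lo must be < z_hi")
  if (is.vector(z)) z <- matrix(z, ncol = 1)
  events <- integer(0); times <- numeric(0); dirs <- integer(0)
  for (m in seq_len(ncol(z))) {
    zm <- z[, m]
    side <- ifelse(zm <= z_lo, -1L, ifelse(zm >= z_hi, 1L, 0L))
    entry <- NA_integer_   # side the molecule entered the slab from
    last <- side[1]
    for (f in 2:length(zm)) {
      if (side[f] == 0L) {
        if (last != 0L) entry <- last
      } else if (side[f] != last) {
        # left the slab (or jumped across it within one frame)
        from <- if (last == 0L) entry else last
        if (!is.na(from) && from != 0L && side[f] == -from ||
            (last != 0L && side[f] == -last)) {
          # completed crossing
          events <- c(events, m)
          times <- c(times, (f - 1) * dt_ns)
          dirs <- c(dirs, side[f])
        }
        entry <- NA_integer_
      }
      last <- side[f]
    }
  }
  total_ns <- (nrow(z) - 1) * dt_ns
  structure(list(events = length(events), molecules = events,
                 event_times = times, directions = dirs,
                 rate_per_100ns = if (total_ns > 0)
                   100 * length(events) / total_ns else NA_real_),
            class = "permeation_record")
}

#' @export
print.permeation_record <- function(x, ...) {
  cat(sprintf("permeation_record: %d events (%.1f per 100 ns)\n",
              x$events, x$rate_per_100ns))
  invisible(x)
}

#' Hydrogen-bond occupancy and partner frequency
#'
#' Geometric hydrogen-bond criterion: donor-acceptor distance below
#' `dist_cut` and donor-H-acceptor angle above `angle_cut`. Occupancy is
#' the fraction of frames in which any partner satisfies the criterion;
#' frequency is the number of distinct partners that ever bind, per unit
#' time.
#'
#' @param donor,hydrogen frames x 3 coordinate matrices of the donor heavy
#'   atom and its hydrogen.
#' @param acceptors frames x partners x 3 array (or frames x 3 matrix for a
#'   single partner) of acceptor coordinates.
#' @param dist_cut donor-acceptor distance cutoff in Angstrom (default 3.5).
#' @param angle_cut donor-H-acceptor angle cutoff in degrees (default 150).
#' @param dt_ns time per frame in ns (default 1).
#' @return list with `occupancy` (fraction of frames bound),
#'   `per_partner` (occupancy per partner), `n_partners` (distinct partners
#'   ever bound) and `frequency_per_ns`.
#' @export
hb_occupancy <- function(donor, hydrogen, acceptors, dist_cut = 3.5,
                         angle_cut = 150, dt_ns = 1) {
  if (length(dim(acceptors)) == 2)
    acceptors <- array(acceptors, c(nrow(acceptors), 1, 3))
  nf <- nrow(donor); np <- dim(acceptors)[2]
  stopifnot(nrow(hydrogen) == nf, dim(acceptors)[1] == nf)
  bound <- matrix(FALSE, nf, np)
  for (p in seq_len(np)) {
    A <- acceptors[, p, ]
    da <- sqrt(rowSums((A - donor)^2))
    v1 <- donor - hydrogen; v2 <- A - hydrogen
    cosang <- rowSums(v1 * v2) /
      (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    bound[, p] <- da < dist_cut & ang > angle_cut
  }
  ever <- colSums(bound) > 0
  total_ns <- nf * dt_ns
  list(occupancy = mean(rowSums(bound) > 0),
       per_partner = colMeans(bound),
       n_partners = sum(ever),
       frequency_per_ns = sum(ever) / total_ns)
}
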