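# Backbone structure container and PDB input.
#
# A `backbone_structure` holds, per residue, the coordinates of the backbone
# atoms N, H, CA, HA, C, O (plus CB when present), as Nres x 3 matrices with
# NA rows for missing atoms, together with flags saying which protons were
# reconstructed geometrically rather than read from file.

.bb_atoms <- c("N", "H", "CA", "HA", "C", "O", "CB")

new_backbone_structure <- function(resno, resname, coords,
                                   h_rebuilt = rep(FALSE, length(resno)),
                                   ha_rebuilt = rep(FALSE, length(resno))) {
  structure(list(resno = as.integer(resno), resname = resname,
                 coords = coords, h_rebuilt = h_rebuilt,
                 ha_rebuilt = ha_rebuilt),
            class = "backbone_structure")
}

#' @export
print.backbone_structure <- function(x, ...) {
  cat("backbone_structure:", length(x$resno), "residues",
      sprintf("(%d H, %d HA rebuilt)\n", sum(x$h_rebuilt), sum(x$ha_rebuilt)))
  invisible(x)
}

#' Read per-residue backbone coordinates from a PDB file
#'
#' Extracts N, H, CA, HA, C, O (and CB) coordinates for each residue of a
#' single-model PDB. Residues missing any of N, CA or C are excluded with a
#' warning; missing amide H or Ha protons are reconstructed geometrically
#' (see [rebuild_protons()]) and flagged.
#'
#' @param path PDB file.
#' @param chain optional chain identifier; default uses all ATOM records.
#' @return a `backbone_structure`.
#' @export
read_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path)),
                  error = function(e) stop("format error reading PDB: ",
                                           conditionMessage(e)))
  at <- pdb$atom[pdb$atom$type == "ATOM", ]
  if (!is.null(chain)) at <- at[at$chain %in% chain, ]
  if (nrow(at) == 0) stop("format error: no ATOM records in ", path)

  resno <- sort(unique(at$resno))
  coords <- lapply(.bb_atoms, function(a) {
    m <- matrix(NA_real_, length(resno), 3)
    # accept HN as a synonym for the amide proton, HA2 for glycine Ha
    names_ok <- switch(a, H = c("H", "HN"), HA = c("HA", "HA2"), a)
    sel <- at[at$elety %in% names_ok, ]
    idx <- match(sel$resno, resno)
    m[idx, ] <- as.matrix(sel[, c("x", "y", "z")])
    m
  })
  names(coords) <- .bb_atoms
  resname <- at$resid[match(resno, at$resno)]

  complete <- !is.na(coords$N[, 1]) & !is.na(coords$CA[, 1]) & !is.na(coords$C[, 1])
  if (!all(complete)) {
    warning("excluding residue(s) missing N/CA/C: ",
            paste(resno[!complete], collapse = ", "))
    coords <- lapply(coords, function(m) m[complete, , drop = FALSE])
    resno <- resno[complete]
    resname <- resname[complete]
  }
  s <- new_backbone_structure(resno, resname, coords)
  rebuild_protons(s)
}

#' Reconstruct missing backbone protons
#'
#' The amide H is placed 1.02 A from N along the external bisector of the
#' C(i-1)-N and CA-N bonds (planar sp2 nitrogen). Ha is placed 1.10 A from
#' CA completing the tetrahedron defined by N, C and CB; when CB is absent
#' the out-of-plane direction on the +N x C side is used. Rebuilt protons
#' are flagged in `h_rebuilt` / `ha_rebuilt`.
#'
#' @param s a `backbone_structure`.
#' @return the structure with protons filled in where geometrically possible.
#' @export
rebuild_protons <- function(s) {
  n <- length(s$resno)
  for (i in seq_len(n)) {
    if (is.na(s$coords$H[i, 1]) && i > 1 &&
        s$resno[i] == s$resno[i - 1] + 1 && !is.na(s$coords$C[i - 1, 1])) {
      Ni <- s$coords$N[i, ]
      u1 <- vnorm(Ni - s$coords$C[i - 1, ])
      u2 <- vnorm(Ni - s$coords$CA[i, ])
      s$coords$H[i, ] <- Ni + 1.02 * vnorm(u1 + u2)
      s$h_rebuilt[i] <- TRUE
    }
    if (is.na(s$coords$HA[i, 1])) {
      CA <- s$coords$CA[i, ]
      u1 <- vnorm(s$coords$N[i, ] - CA)
      u2 <- vnorm(s$coords$C[i, ] - CA)
      if (!is.na(s$coords$CB[i, 1])) {
        u3 <- vnorm(s$coords$CB[i, ] - CA)
        s$coords$HA[i, ] <- CA - 1.10 * vnorm(u1 + u2 + u3)
      } else {
        b <- vnorm(u1 + u2)
        nrm <- vnorm(vcross(u1, u2))
        # tetrahedral split of the remaining two valences about -b
        ct <- cos(109.47 * pi / 180) / sum(-b * u1)
        ct <- min(1, max(-1, ct))
        s$coords$HA[i, ] <- CA + 1.10 * (ct * (-b) + sqrt(max(0, 1 - ct^2)) * nrm)
      }
      s$ha_rebuilt[i] <- TRUE
    }
  }
  s
}

#' Write a backbone structure as PDB
#'
#' @param s a `backbone_structure`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_structure_pdb <- function(s, path) {
  rows <- list()
  for (i in seq_along(s$resno)) {
    for (a in .bb_atoms) {
      xyz <- s$coords[[a]][i, ]
      if (!is.na(xyz[1]))
        rows[[length(rows) + 1]] <- data.frame(
          elety = a, resno = s$resno[i], resid = s$resname[i],
          x = xyz[1], y = xyz[2], z = xyz[3])
    }
  }
  d <- do.call(rbind, rows)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(as.matrix(d[, c("x", "y", "z")]))),
                   resno = d$resno, resid = d$resid, elety = d$elety,
                   chain = rep("A", nrow(d)))
  invisible(path)
}

# standard backbone geometry (lengths in Angstrom, angles in degrees)
.helix_geom <- list(
  b_NCa = 1.458, b_CaC = 1.525, b_CN = 1.329, b_CO = 1.231,
  b_CaCb = 1.530, a_CNCa = 121.7, a_NCaC = 111.2, a_CaCN = 116.2,
  a_CaCO = 120.8, a_NCaCb = 110.5
)

#' Build an ideal alpha-helix
#'
#' Constructs poly-alanine backbone coordinates with standard geometry and
#' helical dihedrals (phi = -57, psi = -47, omega = 180 degrees), including
#' amide H, Ha and CB with L-amino-acid chirality.
#'
#' @param n_res number of residues (>= 2).
#' @param phi,psi backbone dihedrals in degrees.
#' @return a `backbone_structure`.
#' @export
build_ideal_helix <- function(n_res, phi = -57, psi = -47) {
  stopifnot(n_res >= 2)
  g <- .helix_geom
  d2r <- pi / 180
  N <- CA <- C <- O <- H <- HA <- CB <- matrix(NA_real_, n_res, 3)
  # seed the first residue in an arbitrary frame
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_NCa, 0, 0)
  C[1, ] <- nerf_place(c(0, 1, 0), N[1, ], CA[1, ], g$b_CaC,
                       g$a_NCaC * d2r, phi * d2r)
  for (i in seq_len(n_res)) {
    if (i > 1) {
      N[i, ] <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ], g$b_CN,
                           g$a_CaCN * d2r, psi * d2r)
      CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ], g$b_NCa,
                            g$a_CNCa * d2r, pi)   # omega = 180
      C[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ], g$b_CaC,
                           g$a_NCaC * d2r, phi * d2r)
      # CB and HA branch off CA at fixed improper offsets from phi (L-config)
      CB[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ], g$b_CaCb,
                            g$a_NCaCb * d2r, (phi + 122.6) * d2r)
      HA[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ], 1.10,
                            109.5 * d2r, (phi - 119.3) * d2r)
    }
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], g$b_CO,
                         g$a_CaCO * d2r, (psi + 180) * d2r)
  }
  coords <- list(N = N, H = H, CA = CA, HA = HA, C = C, O = O, CB = CB)
  s <- new_backbone_structure(seq_len(n_res), rep("ALA", n_res), coords)
  s <- rebuild_protons(s)
  # the seed residue has no preceding peptide plane; its reconstructed
  # protons come from rebuild_protons where possible
  s$h_rebuilt[] <- FALSE
  s$ha_rebuilt[] <- FALSE
  s
}
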