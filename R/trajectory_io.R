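# Trajectory container and multi-frame readers (PDB / XYZ).
#
# A `trajectory_series` holds coordinates as a frames x atoms x 3 array (A),
# an atom table (name, resno, resname) and the time step per frame in ns.

new_trajectory_series <- function(coords, atoms, dt_ns = 1, box = NULL) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3,
            dim(coords)[2] == nrow(atoms))
  if (dim(coords)[1] < 2) stop("format error: a trajectory needs >= 2 frames")
  structure(list(coords = coords, atoms = atoms, dt_ns = dt_ns, box = box),
            class = "trajectory_series")
}

#' @export
print.trajectory_series <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("trajectory_series: %d frames x %d atoms, dt = %g ns\n",
              d[1], d[2], x$dt_ns))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory_series`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Read a multi-frame trajectory
#'
#' Reads multi-model PDB (MODEL/ENDMDL blocks) or XYZ trajectories into a
#' `trajectory_series`. Atom order in frames after the first may be shuffled
#' as long as (residue number, atom name) identities are consistent; frames
#' are canonicalized to the order of frame 1. An inconsistent atom count
#' across frames is a format error.
#'
#' @param path file ending in `.pdb` or `.xyz`.
#' @param selection optional list with elements `elety` (atom names) and/or
#'   `resno` (residue numbers) restricting the atoms kept. A selection
#'   matching no atom is an error.
#' @param dt_ns time per frame in ns (default 1).
#' @return a `trajectory_series`.
#' @export
read_trajectory <- function(path, selection = NULL, dt_ns = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  tr <- switch(ext,
    pdb = .read_multipdb(path),
    xyz = .read_xyz(path),
    stop("unsupported trajectory format: .", ext))
  atoms <- tr$atoms
  coords <- tr$coords
  if (!is.null(selection)) {
    keep <- rep(TRUE, nrow(atoms))
    if (!is.null(selection$elety)) keep <- keep & atoms$name %in% selection$elety
    if (!is.null(selection$resno)) keep <- keep & atoms$resno %in% selection$resno
    if (!any(keep)) stop("empty selection: no atom matches")
    atoms <- atoms[keep, , drop = FALSE]
    coords <- coords[, keep, , drop = FALSE]
  }
  new_trajectory_series(coords, atoms, dt_ns = dt_ns)
}

# minimal column-oriented reader for multi-model PDB ATOM records; exists to
# support per-frame atom-identity checks and canonical reordering, which
# single-structure readers do not do
.read_multipdb <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0) starts <- 1L
  ends <- c(starts[-1] - 1L, length(lines))
  frames <- list()
  key1 <- NULL; atoms <- NULL
  for (f in seq_along(starts)) {
    blk <- lines[starts[f]:ends[f]]
    rec <- blk[startsWith(blk, "ATOM") | startsWith(blk, "HETATM")]
    if (length(rec) == 0) next
    name <- trimws(substr(rec, 13, 16))
    resname <- trimws(substr(rec, 18, 20))
    resno <- as.integer(trimws(substr(rec, 23, 26)))
    xyz <- cbind(as.numeric(substr(rec, 31, 38)),
                 as.numeric(substr(rec, 39, 46)),
                 as.numeric(substr(rec, 47, 54)))
    key <- paste(resno, name)
    if (is.null(key1)) {
      key1 <- key
      atoms <- data.frame(name = name, resno = resno, resname = resname,
                          stringsAsFactors = FALSE)
    } else {
      if (length(key) != length(key1))
        stop("format error: frame ", length(frames) + 1,
             " has ", length(key), " atoms, frame 1 has ", length(key1))
      idx <- match(key1, key)
      if (anyNA(idx))
        stop("format error: frame ", length(frames) + 1,
             " atom identities do not match frame 1")
      xyz <- xyz[idx, , drop = FALSE]
    }
    frames[[length(frames) + 1]] <- xyz
  }
  if (length(frames) == 0) stop("format error: no ATOM records in ", path)
  coords <- array(NA_real_, c(length(frames), nrow(atoms), 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  list(coords = coords, atoms = atoms)
}

# plain XYZ: repeated blocks of (natoms, comment, natoms lines "name x y z");
# residue numbers are not part of the format and default to the atom index
.read_xyz <- function(path) {
  lines <- readLines(path)
  i <- 1L; frames <- list(); names1 <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    na <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(na)) stop("format error: expected atom count at line ", i)
    if (i + 1L + na > length(lines))
      stop("format error: truncated XYZ frame at line ", i)
    rec <- lines[(i + 2L):(i + 1L + na)]
    parts <- strsplit(trimws(rec), "\\s+")
    name <- vapply(parts, `[`, "", 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (is.null(names1)) names1 <- name
    else if (length(name) != length(names1))
      stop("format error: inconsistent atom count across XYZ frames")
    frames[[length(frames) + 1]] <- xyz
    i <- i + 2L + na
  }
  atoms <- data.frame(name = names1, resno = seq_along(names1),
                      resname = NA_character_, stringsAsFactors = FALSE)
  coords <- array(NA_real_, c(length(frames), length(names1), 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  list(coords = coords, atoms = atoms)
}

#' Write a trajectory in XYZ format
#'
#' @param traj a `trajectory_series`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  na <- dim(traj$coords)[2]
  for (f in seq_len(n_frames(traj))) {
    writeLines(c(as.character(na), sprintf("frame %d", f)), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", traj$atoms$name,
                       traj$coords[f, , 1], traj$coords[f, , 2],
                       traj$coords[f, , 3]), con)
  }
  invisible(path)
}

#' Write a trajectory as multi-model PDB
#'
#' @param traj a `trajectory_series`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  a <- traj$atoms
  resname <- ifelse(is.na(a$resname), "ALA", a$resname)
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL %8d", f), con)
    writeLines(sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                       seq_len(nrow(a)), a$name, resname, a$resno,
                       traj$coords[f, , 1], traj$coords[f, , 2],
                       traj$coords[f, , 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
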