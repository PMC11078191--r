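#' Spectrometer and interaction configuration
#'
#' Collects the field, spinning and interaction constants that enter the
#' 15N relaxation rate models: Larmor frequencies, magic-angle-spinning (MAS)
#' rate, spinlock field, the reduced 15N chemical-shift anisotropy and the
#' rigid-limit bond lengths. The 15N Larmor frequency is derived from the
#' proton frequency through the ratio of gyromagnetic ratios.
#'
#' @param proton_mhz 1H Larmor frequency in MHz (default 800, i.e. an
#'   800-MHz spectrometer).
#' @param mas_khz MAS rate in kHz (default 40).
#' @param spinlock_khz 15N spinlock field in kHz (default 10).
#' @param delta_csa_ppm reduced 15N CSA in ppm (default -170; a common
#'   backbone amide value, configurable because fits depend on it).
#' @param r_nh,r_cah,r_nca rigid-limit bond lengths in Angstrom for the
#'   N-H, Ca-Ha and N-Ca one-bond vectors (defaults 1.02, 1.10, 1.46).
#' @param csa_tilt_deg angle between the 15N CSA symmetry axis and the N-H
#'   bond, in degrees, with the axis kept in the peptide plane (default 17).
#'
#' @return an object of class `spectrometer_config`: a list with the inputs
#'   plus derived angular frequencies (`omega_h`, `omega_n`, `omega_r`,
#'   `omega_1`, all rad/s) and the N-H dipolar coupling `delta_nh` (rad/s).
#' @export
spectrometer_config <- function(proton_mhz = 800, mas_khz = 40,
                                spinlock_khz = 10, delta_csa_ppm = -170,
                                r_nh = 1.02, r_cah = 1.10, r_nca = 1.46,
                                csa_tilt_deg = 17) {
  stopifnot(proton_mhz > 0, mas_khz > 0, spinlock_khz > 0)
  for (r in c(r_nh, r_cah, r_nca)) {
    if (r < 0.9 || r > 2.0)
      stop("bond length ", r, " A outside the physical range [0.9, 2.0] A")
  }
  if (spinlock_khz >= mas_khz / 2)
    warning("spinlock (", spinlock_khz, " kHz) >= MAS/2 (", mas_khz / 2,
            " kHz): rotary-resonance conditions possible")
  # rotary-resonance guard for the R1rho sideband terms
  if (abs(spinlock_khz - mas_khz) < 0.5 || abs(spinlock_khz - 2 * mas_khz) < 0.5)
    warning("spinlock within 500 Hz of a rotary-resonance condition; ",
            "the R1rho sideband spectral densities are near-singular there")

  omega_h <- 2 * pi * proton_mhz * 1e6
  gamma_ratio <- abs(.const$gamma[["N15"]] / .const$gamma[["H1"]])
  cfg <- list(
    proton_mhz = proton_mhz, mas_khz = mas_khz, spinlock_khz = spinlock_khz,
    delta_csa_ppm = delta_csa_ppm,
    r_nh = r_nh, r_cah = r_cah, r_nca = r_nca,
    csa_tilt_deg = csa_tilt_deg,
    omega_h = omega_h,
    omega_n = omega_h * gamma_ratio,
    omega_r = 2 * pi * mas_khz * 1e3,
    omega_1 = 2 * pi * spinlock_khz * 1e3,
    delta_csa = delta_csa_ppm * 1e-6,
    # N-H dipolar coupling strength in rad/s
    delta_nh = 2 * pi * rigid_limit_coupling(r_nh, "NH")
  )
  class(cfg) <- "spectrometer_config"
  cfg
}

#' @export
print.spectrometer_config <- function(x, ...) {
  cat("spectrometer_config:\n")
  cat(sprintf("  1H  %.1f MHz   15N %.2f MHz\n", x$proton_mhz,
              x$omega_n / (2 * pi * 1e6)))
  cat(sprintf("  MAS %.1f kHz   spinlock %.1f kHz\n", x$mas_khz, x$spinlock_khz))
  cat(sprintf("  delta_CSA %.0f ppm   CSA tilt %.0f deg\n",
              x$delta_csa_ppm, x$csa_tilt_deg))
  cat(sprintf("  r(NH) %.2f  r(CaHa) %.2f  r(NCa) %.2f A\n",
              x$r_nh, x$r_cah, x$r_nca))
  invisible(x)
}

#' Secondary-structure segment definitions
#'
#' @param name segment label (e.g. `"TM1"`).
#' @param first_residue,last_residue inclusive residue-number range.
#' @param kind `"helix"` or `"loop"`.
#' @return a one-row data.frame; rbind several to describe a topology.
#' @export
segment_definition <- function(name, first_residue, last_residue,
                               kind = c("helix", "loop")) {
  kind <- match.arg(kind)
  stopifnot(first_residue <= last_residue)
  data.frame(name = name, first_residue = as.integer(first_residue),
             last_residue = as.integer(last_residue), kind = kind,
             stringsAsFactors = FALSE)
}

#' Validate a set of segment definitions
#'
#' Checks ordering within each segment and that segments do not overlap.
#' @param segments data.frame with columns name, first_residue, last_residue, kind.
#' @return the validated data.frame, invisibly.
#' @export
validate_segments <- function(segments) {
  stopifnot(all(c("name", "first_residue", "last_residue", "kind") %in%
                names(segments)))
  if (any(segments$first_residue > segments$last_residue))
    stop("segment with first_residue > last_residue")
  o <- order(segments$first_residue)
  s <- segments[o, ]
  if (nrow(s) > 1 &&
      any(s$first_residue[-1] <= s$last_residue[-nrow(s)]))
    stop("overlapping segment definitions")
  invisible(segments)
}

#' Read / write a run configuration
#'
#' A run configuration is a YAML file holding the spectrometer settings,
#' segment definitions, fit options and the global seed. Every option has a
#' default so a minimal file (or none at all) is valid.
#'
#' @param path YAML file.
#' @return `read_run_config`: a list with elements `spectrometer`
#'   (a [spectrometer_config()]), `segments` (data.frame), `fit` (list of fit
#'   options) and `seed`.
#' @export
read_run_config <- function(path) {
  raw <- if (!is.null(path) && file.exists(path)) yaml::read_yaml(path) else list()
  spec_args <- raw$spectrometer %||% list()
  cfg <- do.call(spectrometer_config, spec_args)
  segs <- if (!is.null(raw$segments)) {
    do.call(rbind, lapply(raw$segments, function(s)
      segment_definition(s$name, s$first_residue, s$last_residue, s$kind)))
  } else NULL
  if (!is.null(segs)) validate_segments(segs)
  fit <- utils::modifyList(default_fit_options(), raw$fit %||% list())
  list(spectrometer = cfg, segments = segs, fit = fit,
       seed = as.integer(raw$seed %||% 0L))
}

#' @rdname read_run_config
#' @param config a list as returned by `read_run_config`.
#' @export
write_run_config <- function(config, path) {
  sp <- config$spectrometer
  out <- list(
    spectrometer = sp[c("proton_mhz", "mas_khz", "spinlock_khz",
                        "delta_csa_ppm", "r_nh", "r_cah", "r_nca",
                        "csa_tilt_deg")],
    segments = if (!is.null(config$segments)) {
      lapply(seq_len(nrow(config$segments)), function(i)
        as.list(config$segments[i, ]))
    },
    fit = config$fit,
    seed = config$seed
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Default fit options
#'
#' Grid bounds and densities for the SMF and 3D GAF searches, Monte-Carlo
#' draw counts and the global seed default.
#' @return named list.
#' @export
default_fit_options <- function() {
  list(
    smf_n_s2 = 200L, smf_n_tau = 200L,
    smf_tau_range = c(1e-11, 1e-2),      # 10 ps .. 10 ms
    smf_chi2_threshold = 10,
    gaf_sigma_max_deg = 25, gaf_sigma_step_deg = 2.5,
    gaf_tau_range = c(1e-9, 1e-5), gaf_n_tau = 25L,
    gaf_delta_step_deg = 15,
    gaf_n_refine = 5L,
    mc_draws = 200L,
    seed = 0L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
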