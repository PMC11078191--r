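# Physical constants (CODATA 2018) used for rigid-limit dipolar couplings.
.const <- list(
  mu0_over_4pi = 1e-7,           # T m / A
  hbar         = 1.054571817e-34, # J s
  # gyromagnetic ratios, rad s^-1 T^-1
  gamma = c(
    H1  = 2.6752218744e8,
    C13 = 6.728284e7,
    N15 = -2.71261804e7
  )
)

#' Gyromagnetic ratio of a nucleus
#'
#' @param nucleus one of `"H1"`, `"C13"`, `"N15"`.
#' @return gyromagnetic ratio in rad s^-1 T^-1 (signed; 15N is negative).
#' @export
gyromagnetic_ratio <- function(nucleus = c("H1", "C13", "N15")) {
  nucleus <- match.arg(nucleus)
  unname(.const$gamma[nucleus])
}

# nuclei involved in each dipolar pair
.pair_nuclei <- function(pair) {
  switch(pair,
    CaHa = c("H1", "C13"),
    NH   = c("H1", "N15"),
    NCa  = c("N15", "C13"),
    stop("unknown dipolar pair: ", pair)
  )
}
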