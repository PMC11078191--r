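---
title: "Collective helix dynamics from ssNMR observables: models, fits and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collective helix dynamics from ssNMR observables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gafdyn` turns per-residue solid-state NMR observables — dipolar order
parameters and ¹⁵N spin relaxation rates — into a quantitative picture of
fast collective helix motion. This vignette is the package's own account of
the models it implements, the conventions and tunable parameters that
matter, what the synthetic-data generators do and do not emulate, and the
design choices made where the problem left the design open.

## The observables and their forward models

**Dipolar order parameters.** A bond vector that fluctuates on timescales
faster than the recoupling period scales its dipolar coupling by the order
parameter S = D_expt / D_rigid, where the rigid limit
D_rigid = (μ₀/4π) γ₁γ₂ ħ / (2π r³) is fixed by the bond length: 1.10 Å for
Cα–Hα (22.70 kHz), 1.46 Å for the one-bond N–Cα (984 Hz) and 1.02 Å for
N–H (11.48 kHz). The bond lengths are configurable in
`spectrometer_config()`; the gyromagnetic ratios are CODATA values.

**TEDOR buildups.** The ¹⁵N–¹³Cα coupling is read from the z-filtered
TEDOR buildup of a ¹⁵N–¹³Cα–¹⁵N three-spin system,

S(t) = Λ(t) · {1 − [J₀(√2 D₁ t)]²} · {1 + [J₀(√2 D₂ t)]²},
Λ(t) = 2^(−N) V₀ λ e^(−Γt),

with D₁ the one-bond and D₂ the two-bond coupling in Hz and N = 2 coupled
¹⁵N spins (N is exposed in the interface for generality). Two numerical
points deserve note. First, the √2 inside the Bessel argument is isolated
in `tedor_signal()` so the alternative reading (a factor 2) can be swapped
in one place; the implemented form puts the first buildup maximum at
t = 2.405/(√2 D₁), which is unit-tested. Second, V₀ and λ enter only as a
product, so the five printed parameters are not jointly identifiable; the
fit pins V₀ (default 1, the generator's value) and frees (λ, Γ, D₁, D₂).
Because J₀ oscillates, the χ² surface in D₁ has local minima; `fit_tedor()`
multi-starts from 10 log-spaced D₁ values between 100 Hz and twice the
rigid limit and keeps the best weighted least-squares solution
(1/σ² weights when per-point errors are given, unweighted otherwise).

**Relaxation decays.** Spinlock series decay as M(t) = M₀e^(−R₁ρt) and
inversion-recovery series as M(t) = M₀(1 − 2e^(−R₁t)). For a fixed rate
the amplitude is linear, so both fits profile M₀ out and search the rate in
one dimension — fast and free of starting-value pathologies even at the
six-point recovery schedule. The 95% interval is residual-resampling Monte
Carlo: residuals are inflated by √(n/(n−2)) (restoring the error variance
that the fit absorbed), resampled with replacement onto the fitted curve,
the pseudo-data refit, and the interval taken as rate ± t₀.₉₇₅(n−2) times
the Monte-Carlo s.d. With 200 seeded draws this is calibrated: across 500
synthetic decays at 2% noise the empirical coverage is 94.2%, which the
acceptance suite checks against the 93–97% band.

## Spectral density and rate models

In a solid there is no overall tumbling, so the spectral density of the
internal motion alone is J(ω) = (2/5)(1 − S²) τ_c / (1 + (ωτ_c)²), which
vanishes identically in the rigid limit S² = 1 and obeys the sum rule
∫₀^∞ J dω = (π/5)(1 − S²). The ¹⁵N rates follow as

- R₁ = (3/4)(δ_CSA ω_N)² J(ω_N) + (δ_NH²/4)[J(ω_H−ω_N) + 3J(ω_N) + 6J(ω_H+ω_N)]
- R₁ρ = ½R₁ + R₁ρ(CSA) + R₁ρ(NH), the rotating-frame terms sampling
  J at ω₁ ± ω_r and ω₁ ± 2ω_r with weights 2/3 and 1/3 (and 3J(ω_H) in the
  dipolar term).

Units are kept in one place: δ_NH is the N–H coupling in rad/s (2π times
the rigid-limit Hz value at r_NH), δ_CSA is dimensionless (ppm × 10⁻⁶) and
multiplies ω_N. Two values the rate models need are not fixed by the
measurement itself and are therefore explicit configuration with common
backbone-amide defaults: the reduced ¹⁵N CSA (−170 ppm) and r_NH (1.02 Å).
A guard warns when the spinlock approaches the rotary-resonance conditions
|ω₁ − ω_r| or |ω₁ − 2ω_r| < 2π·500 Hz, where the sideband terms lose
interpretive meaning. Everything is evaluated through coefficients linear
in (1 − S²), which both the SMF grid and the GAF fit exploit.

**SMF inversion.** One (R₁, R₁ρ) pair constrains two parameters (S², τ_c)
only up to the ratio of two Lorentzians, which generically has two roots:
a nanosecond solution and a 100 µs–ms solution. `fit_smf()` therefore
scans a 200 × 200 grid (S² ∈ [0,1], τ_c log-spaced over 10 ps–10 ms, both
densities configurable), collects *all* local minima, polishes each by
Nelder–Mead, and ranks them; `bimodal` flags solutions on both sides of
1 µs. Zero rates collapse to S² = 1 with τ_c unidentifiable (flagged); a
best χ² above a threshold (default 10) flags "no SMF solution". The χ² is
the weighted sum of the two squared rate residuals — the natural choice
given per-rate uncertainties.

## The 3D GAF model

The collective motion is modelled as rigid-body rocking of a whole
secondary-structure segment about three orthogonal axes (α, β, γ) with
independent Gaussian amplitudes (σ_α, σ_β, σ_γ) and one timescale τ_c.
The squared order parameter of any rank-2 interaction is the closed-form
quintuple sum over Wigner indices; `gaf_kernel()` collapses it into three
5×5 matrix products, so a fit evaluates thousands of (σ, vector) pairs per
second. The closed form corresponds to composing the three axis rotations
in the fixed order R_β·R_α·R_γ applied to the bond vector; the acceptance
suite verifies it against a 2×10⁵-sample Monte-Carlo rotation oracle to
|ΔS²| < 0.01 over a 5×5×5 amplitude grid up to 25°, and axis relabelling
consistency holds to ~10⁻³ at those amplitudes (the composition order is
the only symmetry-breaking term).

**Frames.** Because the motion is collective, one axis triad serves the
whole segment: γ is the helix principal axis (leading singular vector of
the centered Cα coordinates, oriented toward increasing residue numbers),
β is seeded from the first residue's radial direction, and α completes the
right-handed triad. A per-residue frame convention tied to each residue's
own peptide-plane geometry was rejected: on an ideal helix it makes every
residue symmetry-equivalent, collapsing the data onto three distinct
predicted numbers and leaving the six parameters unidentifiable — whereas
the segment frame lets the helical twist spread the bond vectors in
azimuth, which is exactly the information the fit uses. The true
fluctuation axes are still not known a priori, so two fitted angles
(δ_θ, δ_φ) tilt the triad (a polar reorientation: δ_θ toward the in-plane
azimuth δ_φ). In local frame coordinates this tilt is one rotation matrix
shared by all residues, so the optimizer never rebuilds geometry.

**Interaction vectors.** Per residue: Cα–Hα (for S), N–H (for the dipolar
relaxation terms), N–Cα, and the ¹⁵N CSA symmetry axis, which is placed in
the amide plane at a configurable 17° from the N–H bond — the CSA tensor is
treated as axially symmetric and its axis orientation is not measured, so
this common literature value is configuration, not inference. Each
interaction's own S² enters its own spectral density in the rate
predictions; amplitudes alone determine S(CαHα), while τ_c only moves the
rates.

**The fit.** The reduced χ² compares squared Cα–Hα order parameters, R₁ρ
and R₁, each weighted by its stated experimental uncertainty, divided by
N₁+N₂+N₃−p−1 with p = 6. The order-parameter term keeps the S uncertainty
under the S² difference, as the target is defined; note this inflates that
term by roughly (2S)² relative to an uncertainty propagated onto S², so on
correctly-noised synthetic data the expected reduced χ² sits near 2 rather
than 1 — the recovery study checks the ensemble mean over seeds against
[0.5, 2]. The search is deterministic: a full coarse grid (σ in 0–25° by
2.5°, τ_c on a 25-point log grid over 1 ns–10 µs, δ_θ 0–45° and δ_φ in 15°
steps), then Nelder–Mead from the five best nodes, with exact ties broken
toward the smallest Σσ² (parsimony). The (σ, δ) parametrization has a
shallow physical near-degeneracy — tilting the frame while re-mixing the
amplitudes changes the second-moment tensor only at higher order — so
individual fits can trade a ~30° tilt against ~1° amplitude shifts at
equal χ²; across ten noise seeds the amplitudes are still recovered with a
mean absolute error near 1° and τ_c within a few percent.
`gaf_uncertainty()` resamples the observables within their uncertainties
and refits from the converged point for seeded, bit-reproducible 68%
intervals.

## Trajectory observables

- **DCC**: per non-overlapping window, per-atom mean removal, normalized
  covariance of Cα displacement vectors, averaged over windows. Mean
  removal is per window (not per trajectory) — that is what makes the
  short-window/long-window contrast diagnostic of the rocking correlation
  time. Zero-variance atoms yield NA entries (counted in an attribute)
  rather than poisoning neighbours. A guard rejects trajectories whose
  frame-to-frame displacement exceeds half a declared box, since wrapped
  periodic coordinates would corrupt covariances; the package does no
  unwrapping itself.
- **Helix angles**: per-frame principal axis of the segment Cα set,
  sign-fixed by continuity to frame 0 to avoid 180° flips; the angle is
  arccos of the dot product with the frame-0 axis. The reported amplitude
  is the RMS of this series — the deviation about the reference
  orientation — which is the quantity the rocking generator's `rock_sd_deg`
  controls. (Near-)collinear coordinate sets are a geometry error: a
  one-dimensional point cloud has no stable axis-pair convention.
- **Permeation**: a crossing is scored when a molecule enters the membrane
  slab through one boundary and next exits through the other; same-side
  re-exits score nothing; a within-one-frame jump across the whole slab
  counts. Rates are normalized per 100 ns.
- **Hydrogen bonds**: geometric criterion, donor–acceptor distance
  < 3.5 Å and donor–H–acceptor angle > 150° (both configurable; common MD
  practice, since no criterion is dictated by the data). Occupancy is the
  fraction of frames with any bound partner; frequency counts distinct
  partner identities per unit time.

## Synthetic data: what it emulates, what it does not

Each generator is a pure function of its arguments including the seed, and
writes its generating truth next to the data; round-trip tests never let
the fitters see the truth. Defaults are the study conditions used
throughout the tests: the twelve TEDOR dephasing times from 0.57 to
16.57 ms; the sixteen spinlock durations (0–220 ms) and six recovery
delays (0–32 s); a 20-residue ideal α-helix (φ = −57°, ψ = −47°, one extra
leading residue so every data residue has an amide proton) with GAF truth
σ = (8, 12, 6)°, τ_c = 60 ns; relative Gaussian noise of 2% on order
parameters and 5% on rates and curve intensities, mirroring typical
experimental error-bar magnitudes. The rocking generator uses an
Ornstein–Uhlenbeck angle process per perpendicular axis (per-axis s.d.
`rock_sd_deg`/√2 so the tilt RMS equals `rock_sd_deg`; default correlation
time 50 ns) — the minimal stationary Gaussian process with a single
timescale — pivoted 5 Å beyond the helix N-terminus to emulate anchoring
by the connecting loop; that pivot is what gives rocking its positive
within-helix DCC signature. Water paths realize exact crossing schedules
with smooth cosine ramps.

None of this emulates the harder features of real data: spectral overlap
and lineshape fitting, ¹H–¹H coherent contributions, non-Gaussian or
correlated noise, static disorder, multiple motional modes per segment,
lipid dynamics, or periodic-boundary artefacts. Passing tests therefore
demonstrate that the estimators are correct and calibrated under their own
assumptions — not that those assumptions exhaust real spectra or real
trajectories.

## Problem sizes and determinism

The test and acceptance runs use sizes chosen to give each check real
statistical weight while staying light: 2×10⁵ Monte-Carlo rotations per
GAF grid point, ten seeds for the recovery study, 500 decays for CI
calibration, 10⁴-frame trajectories for the DCC bounds. All randomized
procedures take explicit integer seeds (default 0) and are bit-reproducible
given them.

## Known limitations

- The GAF fit assumes one rigid-body mode with a single timescale per
  segment; fast ps–ns internal motions are deliberately neglected, so
  fitted amplitudes absorb (and can slightly overstate) any such residual
  motion.
- Cross-correlated relaxation and multi-timescale extended model-free
  descriptions are out of scope.
- The (σ, δ) near-degeneracy means individual-seed frame angles should not
  be over-interpreted; amplitudes and timescale are the robust outputs.
- The closed-form GAF order parameter fixes one composition order of the
  axis rotations; axis-relabelling symmetry is exact only to ~10⁻³ at
  σ ≤ 25°.
- No chemical-shift, lineshape or spectrum-level processing: the pipeline
  starts at per-peak intensity tables.
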