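# gafdyn

Quantifying fast collective motions of transmembrane α-helices from
solid-state NMR observables — and checking every step against synthetic
data with known ground truth.

Membrane proteins such as the water channel AqpZ show small-amplitude
(~10°) rocking of whole helices on the nanosecond-to-microsecond
timescale. These motions leave three per-residue fingerprints measurable
by ssNMR: the ¹Hα–¹³Cα dipolar order parameter *S*(CαHα), the ¹⁵N
longitudinal rate *R*₁ and the ¹⁵N rotating-frame rate *R*₁ρ under
magic-angle spinning with a spinlock. `gafdyn` implements the full chain
from raw per-peak intensities to fitted collective-motion parameters:

- **TEDOR buildups** (z-filtered, ¹⁵N–¹³Cα–¹⁵N three-spin model):
  *S*(t) = Λ(t){1 − J₀²(√2·D₁t)}{1 + J₀²(√2·D₂t)},
  Λ(t) = 2⁻ᴺ V₀ λ e^(−Γt), fitted by multi-start weighted least squares;
  *S*(NCα) = D₁/D_rigid with D_rigid = (μ₀/4π)γ₁γ₂ħ/(2π r³).
- **Relaxation decays**: M(t) = M₀e^(−R₁ρt) and M(t) = M₀(1 − 2e^(−R₁t)),
  with seeded residual-resampling Monte-Carlo 95% confidence intervals.
- **Rate models**: solid-sample spectral density
  J(ω) = (2/5)(1 − S²)τ_c/(1 + (ωτ_c)²), with R₁ from the ¹⁵N CSA and N–H
  dipolar terms and R₁ρ adding the spinlock/MAS sideband terms at
  ω₁ ± ω_r and ω₁ ± 2ω_r.
- **Simple model-free (SMF) inversion** of each (R₁, R₁ρ) pair on a dense
  (S², τ_c) grid, reporting *all* local minima — the characteristic
  ns versus 100 µs–ms bimodality is surfaced, not silently resolved.
- **3D Gaussian axial fluctuation (GAF) model**: rigid-body rocking of a
  helix about three orthogonal axes with Gaussian amplitudes
  (σ_α, σ_β, σ_γ), one timescale τ_c and two frame-adjustment angles
  (δ_θ, δ_φ); closed-form squared order parameters from the rank-2 Wigner
  algebra; six-parameter reduced-χ² fit (grid search + simplex).
- **Trajectory observables**: windowed dynamic cross-correlation (DCC)
  maps, helix orientation fluctuation, water permeation counting, and
  hydrogen-bond occupancy/partner frequency.
- **Synthetic-data generators** for every input, each a pure function of
  its seed, with the generating truth stored alongside the data.

## Worked example

The `analysis/` scripts run the whole study on synthetic data
(`Rscript analysis/01_simulate.R` … `05_trajectory_obs.R`). The core fit in
`04_gaf_fit.R` condenses to:

```r
library(gafdyn)
cfg <- spectrometer_config()          # 800 MHz, MAS 40 kHz, spinlock 10 kHz
gen <- gen_gaf_helix(n_res = 20, truth = gaf_params(c(8, 12, 6), 60e-9),
                     seed = 0)        # helix + noisy {S_CaHa, R1, R1rho}
fit <- fit_gaf_segment(gen$table, gen$structure, c(2, 21), cfg)
print(fit)
```

```
gaf_fit (residues 2-21):
gaf_params: sigma = (8.5, 11.8, 5.6) deg, tau_c = 5.97e-08 s, delta = (17.4, 117.4) deg
  chi2_red = 1.86 on 53 dof (N1=20, N2=20, N3=20)
```

The fit recovers the generating amplitudes (8, 12, 6)° to within half a
degree and the 60 ns timescale to 0.6%, at a reduced χ² of order 1 — i.e. the
collective-motion model explains the data to within its stated noise. The
earlier stages print the same kind of truth-vs-fit summaries for the TEDOR
couplings (worst error 4.7% at 5% noise), the relaxation rates, the SMF
timescales (40.7, 55.5, 59.6, 73.1, 87.8 ns against truths of 40, 55, 60,
75, 85 ns) and the trajectory observables (DCC mean off-diagonal 0.18 at
2-ns windows versus 0.86 at 2500-ns windows; 12 of 12 scheduled water
crossings counted).

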