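# spinrelax

Dipolar spin-lattice relaxation analysis from molecular trajectories of
two-pool water/macromolecule systems.

## The problem

In myelinated white matter, water confined between the lipid bilayers of
the myelin sheath exchanges magnetization with the membrane hydrogens,
and both compartments relax with rates that are hard to separate
experimentally. Given trajectories of the hydrogen nuclei, the
dipole-dipole contribution to the longitudinal relaxation rate R1 of each
compartment can be computed from first principles: every internuclear
vector is converted to rank-2 spherical harmonics
F_2q(r, θ, φ) ∝ r⁻³, their lag autocorrelations G_q(τ) are estimated,
and the spectral densities

    J_q(ω) = 2 ∫ G_q(τ) cos(ωτ) dτ

evaluated at the Larmor frequency ω_L = γ_H B0 assemble into per-proton
rates

    R1        = (9/8) K² Σ_i [ J_1(ω_L) + J_2(2ω_L) ]           (same pool)
    R1_auto   = (1/16) K² Σ_i [ J_0(0) + 18 J_1(ω_L) + 9 J_2(2ω_L) ]
    R1_cross  = (1/16) K² Σ_i [ 9 J_2(2ω_L) − J_0(0) ]          (other pool)

with K = (μ0/4π) γ_H² ħ. Slowly decaying macromolecular correlations go
through a two-timescale model-free fit
Ĝ(τ) = S² e^(−τ/τ_M) + (1−S²) e^(−τ/τ_i) and its closed-form Lorentzian
spectral density. Pool averages, effective rates R1 + R1_auto, power-law
field-dependence fits n0·B0^n1, hydrogen-weighted sheath averages and
spatial R1/diffusion profiles complete the analysis.

The package is aimed at people analysing membrane/water simulations or
reasoning about compartment relaxation rates: it ships synthetic
trajectory generators (isotropic rotors, cone-restricted rotors,
Brownian translation, water slabs with position-dependent mobility) whose
known ground truth makes every stage of the pipeline testable without a
cluster-scale simulation.

## Worked example

Field-dependence arithmetic from the packaged reference rate table of a
myelin-like membrane/water system (13810 membrane vs 9398 water
hydrogens):

```r
library(spinrelax)
arith <- reproduce_reference_arithmetic()
arith$fit_wp
#> power-law fit: R(B0) = 1.537 * B0^-0.3178 (SSR 0.00103)
arith$fit_mp
#> power-law fit: R(B0) = 6.113 * B0^-0.4498 (SSR 0.0103)
arith$sheath$R1_MS
#> [1] 1.851479
```

The water-pool effective rate falls off as 1.54·B0^−0.32 Hz, the
membrane pool as 6.11·B0^−0.45 Hz, and the hydrogen-weighted average of
the whole sheath at 7 T is 1.85 Hz — the magnetization a
non-compartment-resolving experiment would see.

End-to-end check of the trajectory pipeline against the closed-form
two-spin rate for isotropically tumbling pairs (τ_c = 10 ps, r = 0.158
nm, B0 = 3 T):

```r
spec <- motion_spec("isotropic_rotor", dt = 0.1, n_steps = 5e4, seed = 42,
                    tau_c = 10, pair_distance = 0.158, n_pairs = 8)
tr <- generate_isotropic_rotor(spec)
r  <- pool_r1(tr, protons = seq(1, 16, 2), fields_T = 3,
              truncation_fraction = 0.018, cutoff = 2)
pool_average(r)
#>   pool B0_T n R1_Hz_mean   R1_Hz_se
#> 1   WP    3 8  0.5342286 0.03058387
bpp_r1(0.158, 10, 3)
#> [1] 0.5491216
```

The pipeline estimate (0.534 ± 0.031 Hz) agrees with the analytic 0.549
Hz within its standard error.

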