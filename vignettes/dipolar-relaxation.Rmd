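---
title: "Dipolar spin-lattice relaxation in a two-pool water/macromolecule system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dipolar spin-lattice relaxation in a two-pool water/macromolecule system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinrelax)
```

## The model

`spinrelax` computes the dipole-dipole induced longitudinal relaxation
rate R1 of hydrogen nuclei from their trajectories, in the semiclassical
framework of Bloembergen, Purcell and Pound: molecular motion is treated
classically, the dipolar Hamiltonian quantum mechanically, and the rates
follow from spectral densities of the orientational fluctuations of every
internuclear vector.

For a pair of like spins at distance $r$ with polar angles $(\theta,
\phi)$ relative to the main field (the $z$ axis), the rank-2 spherical
harmonics are

$$F_{2,0} = \frac{1 - 3\cos^2\theta}{r^3}, \qquad
  F_{2,1} = \frac{\sin\theta\cos\theta\, e^{-i\phi}}{r^3}, \qquad
  F_{2,2} = \frac{\sin^2\theta\, e^{-2i\phi}}{r^3},$$

their lag autocorrelations $G_q(\tau) = \mathrm{Re}\,\langle F_q(t)
F_q^*(t + \tau)\rangle_t$, and the spectral densities

$$J_q(\omega) = 2 \int_0^\infty G_q(\tau) \cos(\omega\tau)\, d\tau.$$

The per-proton intra-pool rate sums pairwise spectral densities at the
Larmor frequency $\omega_L = \gamma_H B_0$ and at $2\omega_L$:

$$R_1 = \tfrac{9}{8} K^2 \sum_i \left[ J_{1,i}(\omega_L) +
        J_{2,i}(2\omega_L) \right], \qquad
  K = \frac{\mu_0}{4\pi}\gamma_H^2\hbar.$$

In a hydrated membrane system the hydrogen nuclei split into a water pool
(WP) and a macromolecule pool (MP) with very different absorption
properties, so rates are computed per pool. Interactions *across* the
pools give the auto- and cross-relaxation rates

$$R_1^{auto} = \tfrac{1}{16} K^2 \sum_i \left[ J_{0,i}(0) +
  18 J_{1,i}(\omega_L) + 9 J_{2,i}(2\omega_L) \right], \qquad
  R_1^{cross} = \tfrac{1}{16} K^2 \sum_i \left[ 9 J_{2,i}(2\omega_L) -
  J_{0,i}(0) \right],$$

with the sum over the other pool only. The cross rate is signed and goes
negative in the slow-motion regime where $J_0(0)$ dominates; because both
pool averages contract the same double sum, they satisfy the detailed
balance $N_{WP} R^{cross}_{1,WP} = N_{MP} R^{cross}_{1,MP}$ identically
(`spinrelax` verifies this to machine precision in its tests). The
single-pool observable strips the transfer terms:
$R_1^{ef} = R_1 + R_1^{auto}$ per pool. Field dependence is summarized by
a power-law fit $R^{ef}(B_0) = n_0 B_0^{n_1}$ and the
hydrogen-count-weighted sheath average
$R_{1,MS} = (N_{MP} R^{ef}_{1,MP} + N_{WP} R^{ef}_{1,WP}) /
(N_{MP} + N_{WP})$.

Slowly decaying macromolecular correlations do not vanish within any
affordable trajectory, so they are normalized and fitted to the
two-timescale model-free form

$$\hat G(\tau) = S^2 e^{-\tau/\tau_M} + (1 - S^2) e^{-\tau/\tau_i},$$

whose spectral density is a sum of two Lorentzians scaled by the
magnitude $A_q = G_q(0)$. $S^2 \in [0, 1]$ is the order parameter (1 =
rigid), $\tau_M$ the global and $\tau_i$ the internal correlation time.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `fields_T` | 1.5, 3, 7 | clinical field strengths (tesla) |
| `truncation_fraction` | 0.3 | fraction of the duration kept in $G_q(\tau)$; the tail of a finite-trajectory estimate is noise |
| `window_ns` | 1.5 | short-window length for spatial profiles |
| `n_windows` | 2000 | random windows per profile |
| `mp_subsample_fraction` | 0.1 | fraction of MP protons evaluated (the model-free fit per partner is the expensive step) |
| `pair_distance` | 0.158 nm | intra-pair H-H distance of the synthetic generators (the intramolecular H-H distance in water) |
| `seed` | 1 | master seed; every stochastic draw derives from it |

Units are nm and ps throughout trajectory handling; conversion to SI
(m^-6 s) happens exactly once, at rate assembly, and is enforced by a
`units` attribute so that unconverted spectral densities are rejected
rather than silently mis-scaled by 42 orders of magnitude.

## What the synthetic generators emulate

The generators produce motion with *known* parameters so every stage has
an oracle; they are statistically controlled motion, not physics-grade
molecular dynamics (no force fields, no water chemistry).

* `isotropic_rotor` — rigid H-H pairs whose orientation performs
  rotational Brownian motion via composition of small random rotations
  (per-axis angular variance $2 D_r\, dt$, $D_r = 1/(6\tau_c)$). The
  rank-2 correlation decays as $e^{-\tau/\tau_c}$, so the whole pipeline
  can be checked against the closed-form rate
  $R_1 = \tfrac{3}{10} K^2 r^{-6} [\tau_c/(1 + \omega_L^2\tau_c^2) +
  4\tau_c/(1 + 4\omega_L^2\tau_c^2)]$ (`bpp_r1()`). The small-rotation
  scheme biases the decay once the per-step variance is large, so specs
  with variance $> 0.1$ rad$^2$ are refused.
* `cone_restricted_rotor` — wobble in a cone (half-angle chosen so the
  cone order parameter $[\cos\beta(1+\cos\beta)/2]^2$ equals the target
  $S^2$) riding on global tumbling at $\tau_M$; the ground truth is
  recorded in the trajectory metadata for recovery tests. The internal
  wobble is a reflected spherical diffusion, so its effective correlation
  time is of order, but not exactly, the nominal $\tau_i$; recovery tests
  therefore assert $S^2$ and $\tau_M$, not $\tau_i$.
* `translational_brownian` — free Brownian paths checked against the
  Einstein relation MSD $= 6 D t$.
* `water_slab` — H-H pairs between reflecting walls with
  position-dependent $\tau_c(z)$ and $D(z)$, slower near the walls. This
  emulates the reduced water mobility near a membrane surface and yields
  the corresponding parabola-like R1 profile under the windowed analysis.
  Two caveats: the naive space-dependent-D scheme has no spurious-drift
  correction, so molecules accumulate near the slow walls (the
  *conditional* profiles tested are unaffected); and fast diffusion blurs
  the window-averaged positions, flattening profiles exactly as it does
  in real window analyses.

Passing these suites shows the estimators are correct on motion with the
assumed statistics; it does not validate force-field realism, exchange
kinetics, or intermolecular structure of real membrane water.

## Numerical choices

* **Autocorrelation** — FFT-based with zero padding to $\ge 2N$ (no
  circular wrap) and the unbiased per-lag divisor $N - k$; the real part
  is taken, as stationarity requires. Equality with the direct
  $O(N^2)$ sum is asserted to $10^{-10}$.
* **Spectral densities** — trapezoidal integration on the truncated lag
  grid, no tail extrapolation. Frequencies with $\omega\, dt > \pi/4$
  are refused (the grid cannot resolve the oscillation). The statistical
  error of a single-pair numeric $J$ scales like
  $\sqrt{\tau_{max}/T}$ and is amplified by $(1 + \omega^2\tau_c^2)$ at
  the evaluation frequency. Consequently the validation suites choose
  $\tau_{max} \approx 9\tau_c$ with $T \approx 1000\tau_c$ (truncation
  0.009) for fast rotors, and route slow-motion cases
  ($\omega_L\tau_c > 1$) through the model-free fit — the same split the
  package prescribes for macromolecular protons, whose correlations do
  not decay within the trajectory at all.
* **Model-free fitting** — bounded Levenberg-Marquardt
  (`minpack.lm::nls.lm`) with $S^2 \in [0,1]$,
  $\tau \in [dt, 100\,\tau_{max}]$, a multi-start grid over $S^2$ and
  $\tau_M$ plus an informed start (plateau height, tail log-slope), and
  the best-residual attempt returned. Dense uniform lag grids are
  subsampled log-spaced (at most ~600 points): with 10^4 uniform lags,
  90% of the points sit in the noisy long-lag region and can pull the
  fit into a degenerate minimum. The two-exponential form is symmetric
  under swapping the components, so fits are canonicalized with
  $\tau_M \ge \tau_i$; when the two times coincide within 1% the split
  is unidentifiable and the fit is reported at the $S^2 = 1$ corner with
  the amplitude-weighted time, `tau_i_identifiable = FALSE`. Each
  harmonic order q is fitted independently (the closed form is stated
  per q); recovery tests average the three estimates, which share one
  underlying motion.
* **Power-law fits** — nonlinear least squares in linear space,
  initialized from the log-log regression. Linear space reproduces the
  reference water-pool coefficients from the packaged rate table
  (n0 = 1.54, n1 = -0.32 against the published 1.53, -0.31); a log-space
  fit weights the fields differently and drifts the exponent.
* **Minimum image** — pair vectors use the minimum-image convention
  whenever a periodic box is present; molecule recomposition shifts
  atoms by whole box vectors and never changes minimum-image distances.
* **Partner cutoffs** — optional first-frame distance cutoff for pair
  sums; the $r^{-6}$ weight bounds the truncation error (a 2 nm cutoff
  on 10 nm-spaced synthetic pairs discards contributions below
  $10^{-10}$ of the intra-pair term).

## Problem sizes used in the validation suites

The shipped tests run at desk scale, chosen so each suite finishes in
seconds to a couple of minutes while leaving the assertions comfortably
inside their tolerances: 32 pairs x 10^5 steps for the closed-form rate
equivalence (5%), 16 pairs x 4x10^4 steps for order-parameter recovery
($S^2 \pm 0.05$, $\tau_M \pm 15\%$), 100 particles x 10^4 steps for
diffusion recovery (5%), and a 40-molecule, 10 ns slab with 400 windows
of 500 ps for the spatial profile (wall vs centre at >3 standard
errors). The reference-table arithmetic (effective rates, power-law
fits, sheath average, detailed balance) is exact given its inputs.

## Known limitations

* Chemical exchange is outside the scope of trajectory analysis;
  `exchange_total()` only adds a user-supplied exchange rate to the
  computed dipolar cross rate.
* No orientation-dependence study of the membrane normal relative to
  B0; the frame convention fixes B0 along z.
* Numeric spectral densities carry integrated-tail noise on short
  trajectories; use the model-free route for slowly decaying
  correlations.
* The internal trajectory format and GRO are the supported formats;
  compressed binary trajectory formats are not read.
* Only orthorhombic periodic boxes are supported.
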