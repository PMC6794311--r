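Package: spinrelax
Title: Dipolar Spin-Lattice Relaxation Analysis from Molecular Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes dipole-dipole induced longitudinal (R1) relaxation
    rates of hydrogen nuclei from molecular trajectories of a two-pool
    water/macromolecule system such as the myelin sheath. Trajectories of
    hydrogen positions are converted to second-rank spherical harmonics,
    lag autocorrelation functions and spectral densities; per-proton and
    pool-averaged intrinsic, auto- and cross-relaxation rates are assembled
    at arbitrary magnetic field strengths, together with model-free
    (order-parameter) fits for slowly decaying macromolecular correlations,
    spatial relaxation and diffusion profiles, power-law field-dependence
    fits and hydrogen-weighted compartment averages. Includes generators of
    synthetic trajectories (isotropic rotors, cone-restricted rotors,
    translational Brownian motion, water slabs with position-dependent
    mobility) with known ground-truth motional parameters for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
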