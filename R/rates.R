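#' Intra-pool R1 from summed spectral densities
#'
#' Assembles the per-proton longitudinal rate
#' \deqn{R_1 = \frac{9}{8} K^2 \sum_i \left[ J_{1,i}(\omega_L) +
#' J_{2,i}(2\omega_L) \right]}
#' with \eqn{K = (\mu_0/4\pi)\gamma_H^2\hbar}. Spectral densities must be
#' in SI units (m^-6 s, see [as_si_J()]); passing nm-based values is an
#' error rather than a silent factor-1e42 bug.
#'
#' @param J1 per-partner `J_1(omega_L)` values, SI (m^-6 s).
#' @param J2 per-partner `J_2(2 omega_L)` values, SI.
#' @param field a [field_spec()] (documents the frequency the J values
#'   were evaluated at).
#' @return rate in Hz.
#' @export
r1_pair_sum <- function(J1, J2, field) {
  .assert_si_J(J1); .assert_si_J(J2)
  stopifnot(inherits(field, "field_spec"))
  (9 / 8) * dipolar_prefactor()^2 * (sum(J1) + sum(J2))
}

#' Auto- and cross-relaxation from summed cross-pool spectral densities
#'
#' \deqn{R_1^{auto} = \frac{1}{16} K^2 \sum_i \left[ J_{0,i}(0) +
#' 18 J_{1,i}(\omega_L) + 9 J_{2,i}(2\omega_L) \right]}
#' \deqn{R_1^{cross} = \frac{1}{16} K^2 \sum_i \left[ 9 J_{2,i}(2\omega_L)
#' - J_{0,i}(0) \right]}
#' The partner sum runs over nuclei of the *other* pool only. The cross
#' rate is signed: it goes negative in the slow-motion regime where
#' `J_0(0)` dominates.
#'
#' @param J0 per-partner `J_0(0)` values, SI (m^-6 s).
#' @param J1 per-partner `J_1(omega_L)` values, SI.
#' @param J2 per-partner `J_2(2 omega_L)` values, SI.
#' @param field a [field_spec()].
#' @return list with `auto` and `cross` rates in Hz.
#' @export
auto_cross_pair_sum <- function(J0, J1, J2, field) {
  .assert_si_J(J0); .assert_si_J(J1); .assert_si_J(J2)
  stopifnot(inherits(field, "field_spec"))
  pref <- dipolar_prefactor()^2 / 16
  list(auto = pref * (sum(J0) + 18 * sum(J1) + 9 * sum(J2)),
       cross = pref * (9 * sum(J2) - sum(J0)))
}

## partner indices for proton j: same or other pool, optional first-frame
## minimum-image distance cutoff (r^-6 makes distant partners negligible)
.partners <- function(traj, j, scope = c("same", "other"), cutoff = NULL) {
  scope <- match.arg(scope)
  pj <- traj$pool[j]
  if (is.na(pj)) stop("proton ", j, " has no pool assignment")
  idx <- if (scope == "same") which(traj$pool == pj & seq_len(n_atoms(traj)) != j)
  else which(!is.na(traj$pool) & traj$pool != pj)
  if (!is.null(cutoff) && length(idx)) {
    d <- sweep(traj$coords[1, idx, , drop = FALSE][1, , , drop = TRUE],
               2, traj$coords[1, j, ])
    if (is.null(dim(d))) d <- matrix(d, ncol = 3)
    if (!is.null(traj$box))
      for (ax in 1:3)
        d[, ax] <- d[, ax] - traj$box[ax] * round(d[, ax] / traj$box[ax])
    idx <- idx[sqrt(rowSums(d^2)) <= cutoff]
  }
  idx
}

## summed pairwise spectral densities for one proton at a set of angular
## frequencies (rad/s); returns matrix [length(omega) x 3] in nm^-6 ps
.proton_J_sums <- function(traj, j, partners, omega,
                           truncation_fraction = 0.3,
                           method = c("numeric", "modelfree")) {
  method <- match.arg(method)
  Jsum <- matrix(0, length(omega), 3,
                 dimnames = list(NULL, c("J0", "J1", "J2")))
  for (i in partners) {
    cf <- autocorrelate(harmonics_from_polar(pair_polar_series(traj, j, i)),
                        truncation_fraction)
    if (method == "numeric") {
      Ji <- spectral_density_numeric(cf, omega)
      Jsum <- Jsum + as.matrix(Ji[, c("J0", "J1", "J2")])
    } else {
      fits <- fit_modelfree(cf)
      for (k in 1:3)
        Jsum[, k] <- Jsum[, k] +
          as.numeric(spectral_density_modelfree(fits[[k]], omega,
                                                override = TRUE))
    }
  }
  Jsum
}

#' Per-proton intra-pool relaxation rates
#'
#' Runs the full chain (polar coordinates, spherical harmonics, lag
#' autocorrelation, spectral density, rate assembly) for each selected
#' proton, summing over all partner nuclei of the same pool. The water
#' pool uses numeric integration of the correlation functions; for
#' macromolecular protons whose correlations do not decay within the
#' trajectory, use `method = "modelfree"` to go through the
#' order-parameter fit instead.
#'
#' @param traj a pool-assigned [spin_trajectory()].
#' @param protons indices of the protons to evaluate; default all
#'   pool-assigned protons.
#' @param fields_T numeric vector of field strengths in tesla.
#' @param truncation_fraction lag truncation for [autocorrelate()].
#' @param cutoff optional partner distance cutoff in nm (first-frame
#'   minimum-image distance); `NULL` sums all pool partners.
#' @param method `"numeric"` or `"modelfree"` spectral densities.
#' @return data.frame with columns `proton`, `pool`, `B0_T`, `R1_Hz`.
#' @export
pool_r1 <- function(traj, protons = NULL, fields_T = c(1.5, 3, 7),
                    truncation_fraction = 0.3, cutoff = NULL,
                    method = c("numeric", "modelfree")) {
  stopifnot(inherits(traj, "spin_trajectory"))
  method <- match.arg(method)
  if (is.null(protons)) protons <- which(!is.na(traj$pool))
  fields <- lapply(fields_T, field_spec)
  wL <- vapply(fields, function(f) f$omega_L, 0)
  omega <- c(wL, 2 * wL)
  out <- vector("list", length(protons))
  for (k in seq_along(protons)) {
    j <- protons[k]
    part <- .partners(traj, j, "same", cutoff)
    if (!length(part)) stop("proton ", j, " has no pool partners")
    Jsum <- .proton_J_sums(traj, j, part, omega, truncation_fraction,
                           method)
    nf <- length(fields_T)
    r1 <- vapply(seq_len(nf), function(f)
      r1_pair_sum(as_si_J(Jsum[f, "J1"]), as_si_J(Jsum[nf + f, "J2"]),
                  fields[[f]]), 0)
    out[[k]] <- data.frame(proton = j, pool = traj$pool[j],
                           B0_T = fields_T, R1_Hz = r1)
  }
  do.call(rbind, out)
}

#' Per-proton cross-pool auto- and cross-relaxation rates
#'
#' Same machinery as [pool_r1()] but partner sums run over the *other*
#' pool and the q = 0 spectral density at zero frequency enters. Cross
#' rates are signed.
#'
#' @inheritParams pool_r1
#' @return data.frame with columns `proton`, `pool`, `B0_T`, `auto_Hz`,
#'   `cross_Hz`.
#' @export
cross_pool_rates <- function(traj, protons = NULL, fields_T = c(1.5, 3, 7),
                             truncation_fraction = 0.3, cutoff = NULL) {
  stopifnot(inherits(traj, "spin_trajectory"))
  if (is.null(protons)) protons <- which(!is.na(traj$pool))
  fields <- lapply(fields_T, field_spec)
  wL <- vapply(fields, function(f) f$omega_L, 0)
  omega <- c(0, wL, 2 * wL)
  out <- vector("list", length(protons))
  for (k in seq_along(protons)) {
    j <- protons[k]
    part <- .partners(traj, j, "other", cutoff)
    if (!length(part)) stop("proton ", j, " has no cross-pool partners")
    Jsum <- .proton_J_sums(traj, j, part, omega, truncation_fraction)
    nf <- length(fields_T)
    ac <- lapply(seq_len(nf), function(f)
      auto_cross_pair_sum(as_si_J(Jsum[1, "J0"]),
                          as_si_J(Jsum[1 + f, "J1"]),
                          as_si_J(Jsum[1 + nf + f, "J2"]), fields[[f]]))
    out[[k]] <- data.frame(proton = j, pool = traj$pool[j],
                           B0_T = fields_T,
                           auto_Hz = vapply(ac, `[[`, 0, "auto"),
                           cross_Hz = vapply(ac, `[[`, 0, "cross"))
  }
  do.call(rbind, out)
}

#' Random proton subsample of a pool
#'
#' @param traj a pool-assigned [spin_trajectory()].
#' @param pool `"WP"` or `"MP"`.
#' @param fraction fraction of the pool to select (ignored if `n` given).
#' @param n absolute number to select.
#' @param seed RNG seed for the draw.
#' @return integer vector of proton indices.
#' @export
subsample_protons <- function(traj, pool, fraction = 0.1, n = NULL,
                              seed = 1L) {
  idx <- which(traj$pool == pool)
  if (!length(idx)) stop("pool ", pool, " is empty")
  if (is.null(n)) n <- max(1L, round(fraction * length(idx)))
  .with_seed(seed, sort(sample(idx, min(n, length(idx)))))
}

#' Pool averages of per-proton rates
#'
#' Averages per-proton rate columns within each (pool, field) group and
#' reports standard errors and group sizes.
#'
#' @param rates data.frame with columns `pool`, `B0_T` and one or more
#'   numeric rate columns (e.g. from [pool_r1()]).
#' @param value_cols names of the rate columns; default every numeric
#'   column except `proton` and `B0_T`.
#' @return data.frame with per-group `mean`, `se` and `n` for each value
#'   column.
#' @export
pool_average <- function(rates, value_cols = NULL) {
  if (!nrow(rates)) stop("empty rate table")
  if (is.null(value_cols))
    value_cols <- setdiff(names(rates)[vapply(rates, is.numeric, TRUE)],
                          c("proton", "B0_T"))
  groups <- split(rates, list(rates$pool, rates$B0_T), drop = TRUE)
  out <- lapply(groups, function(g) {
    row <- data.frame(pool = g$pool[1], B0_T = g$B0_T[1],
                      n = nrow(g))
    for (vc in value_cols) {
      row[[paste0(vc, "_mean")]] <- mean(g[[vc]])
      row[[paste0(vc, "_se")]] <- stats::sd(g[[vc]]) / sqrt(nrow(g))
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$pool, out$B0_T), ]
}

#' Effective relaxation rates
#'
#' The effective rate of a pool strips the magnetization-transfer terms:
#' \eqn{R_1^{ef} = R_1 + R_1^{auto}} (the cross rate moves magnetization
#' between the pools and drops out of the single-pool observable).
#'
#' @param rate_table data.frame with columns `B0_T`, `pool`, `intra_Hz`,
#'   `auto_Hz` (e.g. [reference_rate_table()]).
#' @return the table with an added `effective_Hz` column.
#' @export
effective_rates <- function(rate_table) {
  stopifnot(all(c("B0_T", "pool", "intra_Hz", "auto_Hz") %in%
                  names(rate_table)))
  rate_table$effective_Hz <- rate_table$intra_Hz + rate_table$auto_Hz
  rate_table
}

#' Power-law fit of the field dependence
#'
#' Fits \eqn{R(B_0) = n_0 B_0^{n_1}} by nonlinear least squares in linear
#' space, initialized from the log-log regression solution. Two points
#' are interpolated exactly.
#'
#' @param B0 field strengths in tesla (>= 2 distinct values).
#' @param rate rates in Hz (must be positive).
#' @return object of class `power_law_fit`: list with `n0` (Hz T^-n1),
#'   `n1`, `residual` (SSR), and the data.
#' @export
fit_power_law <- function(B0, rate) {
  if (length(B0) != length(rate) || length(unique(B0)) < 2)
    stop("need rates at >= 2 distinct field strengths")
  if (any(rate <= 0)) stop("rates must be positive for a power-law fit")
  init <- stats::coef(stats::lm(log(rate) ~ log(B0)))
  fit <- minpack.lm::nlsLM(rate ~ n0 * B0^n1,
                           start = list(n0 = exp(init[[1]]),
                                        n1 = init[[2]]),
                           control = minpack.lm::nls.lm.control(
                             maxiter = 500, ptol = 1e-12, ftol = 1e-12))
  co <- stats::coef(fit)
  structure(list(n0 = unname(co[["n0"]]), n1 = unname(co[["n1"]]),
                 residual = sum(stats::resid(fit)^2),
                 data = data.frame(B0 = B0, rate = rate)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power-law fit: R(B0) = %.4g * B0^%.4g (SSR %.3g)\n",
              x$n0, x$n1, x$residual))
  invisible(x)
}

#' @export
predict.power_law_fit <- function(object, B0, ...) {
  object$n0 * B0^object$n1
}

#' Hydrogen-weighted average rate of the whole sheath
#'
#' \deqn{R_{1,MS}(B_0) = \frac{N_{MP} R^{ef}_{1,MP}(B_0) +
#' N_{WP} R^{ef}_{1,WP}(B_0)}{N_{MP} + N_{WP}}}
#' where the effective rates come from the fitted power laws and the
#' weights are the hydrogen counts of the two pools.
#'
#' @param fit_wp,fit_mp [fit_power_law()] fits of the effective WP and MP
#'   rates.
#' @param n_wp,n_mp hydrogen counts of the pools.
#' @param B0 field strength in tesla.
#' @return list with `R1_MS` (Hz), the per-pool effective rates at `B0`
#'   and the weights.
#' @export
sheath_average <- function(fit_wp, fit_mp, n_wp, n_mp, B0) {
  stopifnot(inherits(fit_wp, "power_law_fit"),
            inherits(fit_mp, "power_law_fit"))
  r_wp <- predict(fit_wp, B0)
  r_mp <- predict(fit_mp, B0)
  list(R1_MS = (n_mp * r_mp + n_wp * r_wp) / (n_mp + n_wp),
       R1_WP_ef = r_wp, R1_MP_ef = r_mp, n_wp = n_wp, n_mp = n_mp,
       B0 = B0)
}

#' Total water-to-macromolecule exchange rate
#'
#' The total magnetization exchange rate out of the water pool is the sum
#' of the dipolar cross-relaxation rate and the chemical-exchange
#' contribution: `k_WP = R1_cross_WP + R_ce`. Chemical exchange is not
#' computable from classical trajectories and must be supplied (e.g. from
#' magnetization-transfer experiments).
#'
#' @param cross_wp dipolar cross-relaxation rate of the water pool, Hz
#'   (may be negative in the slow-motion regime; flagged).
#' @param R_ce chemical-exchange contribution, Hz.
#' @return list with `k_WP` (Hz), `cross_fraction` (share of the dipolar
#'   term) and `negative_cross` flag.
#' @export
exchange_total <- function(cross_wp, R_ce) {
  k <- cross_wp + R_ce
  list(k_WP = k,
       cross_fraction = if (k != 0) cross_wp / k else NA_real_,
       negative_cross = cross_wp < 0)
}

#' Spatial relaxation and diffusion profile from short windows
#'
#' Repeats the relaxation analysis on many short, randomly placed
#' trajectory windows so that each estimate can be attributed to the
#' average position of the molecule during the window; binning the
#' estimates by position yields spatial R1 and diffusion profiles (the
#' window must be short enough that molecules do not traverse the slab,
#' long enough for the correlation functions to decay). Each window picks
#' one random molecule and computes its intra-pair R1 (numeric spectral
#' densities) and its MSD-slope diffusion coefficient.
#'
#' @param traj a [spin_trajectory()] of H-H pair molecules (e.g. a water
#'   slab).
#' @param window_ps window length in ps (must not exceed the trajectory).
#' @param n_windows number of random windows.
#' @param field a [field_spec()].
#' @param n_bins number of equal-width z bins.
#' @param z_range range of the slab coordinate; defaults to the slab
#'   width in the metadata, else the data range.
#' @param truncation_fraction lag truncation within each window.
#' @param seed RNG seed for window placement.
#' @return data.frame with per-bin `z_mid`, `n`, `R1_mean`, `R1_se`,
#'   `D_mean`, `D_se` (D in cm^2/s).
#' @export
windowed_profile <- function(traj, window_ps, n_windows, field,
                             n_bins = 8, z_range = NULL,
                             truncation_fraction = 0.3, seed = 1L) {
  stopifnot(inherits(traj, "spin_trajectory"),
            inherits(field, "field_spec"))
  nf <- n_frames(traj)
  wframes <- round(window_ps / traj$dt) + 1L
  if (wframes > nf)
    stop("window (", window_ps, " ps) longer than trajectory (",
         duration_ps(traj), " ps)")
  if (wframes < 20) stop("window too short for correlation analysis")
  mols <- unique(traj$molecule_id)
  pairs <- lapply(mols, function(m) which(traj$molecule_id == m))
  pairs <- pairs[vapply(pairs, length, 0L) == 2L]
  if (!length(pairs)) stop("no two-proton molecules in trajectory")
  if (is.null(z_range))
    z_range <- if (!is.null(traj$metadata$slab_width))
      c(0, traj$metadata$slab_width) else range(traj$coords[, , 3])
  draws <- .with_seed(seed, data.frame(
    mol = sample(length(pairs), n_windows, replace = TRUE),
    start = sample(nf - wframes + 1L, n_windows, replace = TRUE)))
  res <- matrix(NA_real_, n_windows, 3,
                dimnames = list(NULL, c("z", "R1", "D")))
  for (w in seq_len(n_windows)) {
    ij <- pairs[[draws$mol[w]]]
    rows <- draws$start[w]:(draws$start[w] + wframes - 1L)
    sub <- spin_trajectory(traj$coords[rows, ij, , drop = FALSE],
                           traj$dt, species = traj$species[ij],
                           molecule_id = traj$molecule_id[ij],
                           pool = traj$pool[ij], box = traj$box)
    cf <- autocorrelate(harmonics_from_polar(
      pair_polar_series(sub, 1, 2)), truncation_fraction)
    J <- spectral_density_numeric(cf, c(field$omega_L, 2 * field$omega_L))
    res[w, "R1"] <- r1_pair_sum(as_si_J(J$J1[1]), as_si_J(J$J2[2]), field)
    res[w, "z"] <- mean(traj$coords[rows, ij, 3])
    res[w, "D"] <- estimate_diffusion(sub)$D
  }
  edges <- seq(z_range[1], z_range[2], length.out = n_bins + 1L)
  bin <- cut(res[, "z"], edges, include.lowest = TRUE)
  out <- do.call(rbind, lapply(levels(bin), function(b) {
    sel <- which(bin == b)
    k <- match(b, levels(bin))
    data.frame(z_mid = (edges[k] + edges[k + 1]) / 2, n = length(sel),
               R1_mean = mean(res[sel, "R1"]),
               R1_se = stats::sd(res[sel, "R1"]) /
                 sqrt(max(1, length(sel))),
               D_mean = mean(res[sel, "D"]),
               D_se = stats::sd(res[sel, "D"]) / sqrt(max(1, length(sel))))
  }))
  rownames(out) <- NULL
  out
}
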