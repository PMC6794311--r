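#' Reference pool-averaged rate table for the myelin membrane system
#'
#' Pool-averaged intrinsic, cross- and auto-relaxation rates of the
#' two-pool myelin membrane/water system at 1.5, 3 and 7 T, as obtained
#' from a 20 ns all-atom simulation of the two-leaflet membrane patch
#' (see [myelin_composition()]). Shipped as a plain-text fixture; all
#' field-dependence and sheath-average arithmetic in
#' [reproduce_reference_arithmetic()] starts from these numbers.
#'
#' @return data.frame with columns `B0_T`, `pool`, `intra_Hz`,
#'   `cross_Hz`, `auto_Hz`.
#' @export
reference_rate_table <- function() {
  utils::read.csv(system.file("extdata", "table1_rates.csv",
                              package = "spinrelax"),
                  stringsAsFactors = FALSE)
}

#' Derived quantities from a pool-averaged rate table
#'
#' Everything that follows from the printed pool averages alone:
#' effective rates per pool and field, the power-law field-dependence
#' fits \eqn{R^{ef}(B_0) = n_0 B_0^{n_1}}, the hydrogen-weighted sheath
#' average at a reference field, the field-dependence decrease factors,
#' and the detailed-balance check
#' \eqn{N_{WP} R^{cross}_{1,WP} \approx N_{MP} R^{cross}_{1,MP}}.
#'
#' @param rate_table a rate table shaped like [reference_rate_table()]
#'   (default).
#' @param n_wp,n_mp hydrogen counts of the water and macromolecule pools.
#' @param B0_ref field at which the sheath average is evaluated (T).
#' @return list with elements `effective` (table with `effective_Hz`),
#'   `fit_wp`, `fit_mp` ([fit_power_law()] objects), `sheath`
#'   ([sheath_average()] result at `B0_ref`), `cross_ratio_wp` (lowest
#'   over highest field), `decrease_factors` (per pool and rate type),
#'   and `balance` (both sides of the detailed-balance identity and their
#'   relative imbalance).
#' @export
reproduce_reference_arithmetic <- function(rate_table = reference_rate_table(),
                                           n_wp = 9398, n_mp = 13810,
                                           B0_ref = 7) {
  eff <- effective_rates(rate_table)
  wp <- eff[eff$pool == "WP", ]
  mp <- eff[eff$pool == "MP", ]
  wp <- wp[order(wp$B0_T), ]
  mp <- mp[order(mp$B0_T), ]
  fit_wp <- fit_power_law(wp$B0_T, wp$effective_Hz)
  fit_mp <- fit_power_law(mp$B0_T, mp$effective_Hz)
  sheath <- sheath_average(fit_wp, fit_mp, n_wp, n_mp, B0_ref)
  lo <- which.min(wp$B0_T); hi <- which.max(wp$B0_T)
  decrease <- data.frame(
    pool = c("WP", "WP", "MP", "MP"),
    quantity = c("intra", "cross", "intra", "auto"),
    factor = c(wp$intra_Hz[lo] / wp$intra_Hz[hi],
               wp$cross_Hz[lo] / wp$cross_Hz[hi],
               mp$intra_Hz[lo] / mp$intra_Hz[hi],
               mp$auto_Hz[lo] / mp$auto_Hz[hi]))
  lhs <- n_wp * wp$cross_Hz
  rhs <- n_mp * mp$cross_Hz
  list(effective = eff, fit_wp = fit_wp, fit_mp = fit_mp,
       sheath = sheath,
       cross_ratio_wp = wp$cross_Hz[lo] / wp$cross_Hz[hi],
       decrease_factors = decrease,
       balance = data.frame(B0_T = wp$B0_T, lhs = lhs, rhs = rhs,
                            rel_imbalance = (lhs - rhs) /
                              pmax(abs(lhs), abs(rhs))))
}

#' Analysis configuration
#'
#' Bundles the tunable parameters of the full pipeline with their
#' defaults: field strengths 1.5/3/7 T, lag truncation at 30% of the
#' trajectory duration, 1.5 ns analysis windows, 2000 random windows for
#' spatial profiles, a 10% macromolecular proton subsample, and one
#' master seed.
#'
#' @param fields_T field strengths in tesla.
#' @param truncation_fraction lag truncation fraction in (0, 1].
#' @param window_ns short-window length in ns for spatial profiles.
#' @param n_windows number of random windows.
#' @param mp_subsample_fraction fraction of MP protons evaluated.
#' @param seed master seed.
#' @param input path to a trajectory file (internal format), or `NULL`
#'   when a generator spec is supplied to [run_pipeline()].
#' @param outdir output directory for the CSV/manifest bundle.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(fields_T = c(1.5, 3, 7),
                            truncation_fraction = 0.3,
                            window_ns = 1.5, n_windows = 2000,
                            mp_subsample_fraction = 0.1, seed = 1L,
                            input = NULL, outdir = tempfile("spinrelax_")) {
  stopifnot(truncation_fraction > 0, truncation_fraction <= 1,
            all(fields_T > 0), n_windows >= 1,
            mp_subsample_fraction > 0, mp_subsample_fraction <= 1)
  structure(list(fields_T = fields_T,
                 truncation_fraction = truncation_fraction,
                 window_ns = window_ns, n_windows = n_windows,
                 mp_subsample_fraction = mp_subsample_fraction,
                 seed = as.integer(seed), input = input, outdir = outdir),
            class = "analysis_config")
}

#' Run the relaxation pipeline on a trajectory
#'
#' Orchestrates generate/load, pool relaxation rates, pool averages,
#' effective rates and the power-law field fit, and writes a CSV report
#' bundle plus a JSON manifest echoing the resolved configuration. When
#' the trajectory metadata carries a ground-truth rotational correlation
#' time (isotropic-rotor fixtures), the report additionally compares the
#' pipeline rates with the closed-form two-spin prediction.
#'
#' @param config an [analysis_config()]; `config$input` names an
#'   internal-format trajectory unless `spec` is given.
#' @param spec optional [motion_spec()] generated in place of reading
#'   `config$input`.
#' @param cutoff optional partner cutoff in nm passed to [pool_r1()].
#' @return list with `rates` (per proton), `averages`, `fit` (power-law
#'   fit of the pool-averaged rates, if >= 2 fields), `closed_form`
#'   (data.frame or `NULL`), and `files` (paths written).
#' @export
run_pipeline <- function(config, spec = NULL, cutoff = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  traj <- if (!is.null(spec)) {
    switch(spec$kind,
           isotropic_rotor = generate_isotropic_rotor(spec),
           cone_restricted_rotor = generate_cone_restricted_rotor(spec),
           translational_brownian = generate_translational_brownian(spec),
           water_slab = generate_water_slab(spec))
  } else {
    if (is.null(config$input))
      stop("config$input is NULL and no generator spec was supplied")
    if (!file.exists(config$input))
      stop("input trajectory not found: ", config$input)
    read_trajectory(config$input, "internal")
  }
  rates <- tryCatch(
    pool_r1(traj, fields_T = config$fields_T,
            truncation_fraction = config$truncation_fraction,
            cutoff = cutoff),
    error = function(e) stop("stage pool_r1 failed: ", conditionMessage(e)))
  avg <- pool_average(rates)
  fit <- NULL
  if (length(unique(rates$B0_T)) >= 2) {
    wp_avg <- avg[avg$pool == avg$pool[1], ]
    fit <- fit_power_law(wp_avg$B0_T, wp_avg$R1_Hz_mean)
  }
  closed <- NULL
  if (identical(traj$metadata$kind, "isotropic_rotor")) {
    closed <- data.frame(
      B0_T = config$fields_T,
      R1_closed_Hz = vapply(config$fields_T, function(b)
        bpp_r1(traj$metadata$pair_distance, traj$metadata$tau_c, b), 0))
    closed$R1_pipeline_Hz <-
      avg$R1_Hz_mean[match(closed$B0_T, avg$B0_T)]
    closed$rel_error <- closed$R1_pipeline_Hz / closed$R1_closed_Hz - 1
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  files <- c(rates = file.path(config$outdir, "rates_per_proton.csv"),
             averages = file.path(config$outdir, "rates_pool_average.csv"),
             manifest = file.path(config$outdir, "manifest.json"))
  utils::write.csv(rates, files[["rates"]], row.names = FALSE)
  utils::write.csv(avg, files[["averages"]], row.names = FALSE)
  if (!is.null(closed)) {
    files[["closed_form"]] <- file.path(config$outdir, "closed_form.csv")
    utils::write.csv(closed, files[["closed_form"]], row.names = FALSE)
  }
  manifest <- list(config = unclass(config),
                   generator = if (!is.null(spec)) unclass(spec)[
                     !vapply(spec, is.function, TRUE)] else NULL,
                   package_version =
                     as.character(utils::packageVersion("spinrelax")))
  jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE, digits = NA)
  list(rates = rates, averages = avg, fit = fit, closed_form = closed,
       files = files)
}

#' Closed-form two-spin R1 (rigid isotropic rotor)
#'
#' The classical closed form for a rigid pair of like spins tumbling
#' isotropically:
#' \deqn{R_1 = \frac{3}{10} K^2 r^{-6} \left[
#' \frac{\tau_c}{1 + \omega_L^2\tau_c^2} +
#' \frac{4\tau_c}{1 + 4\omega_L^2\tau_c^2} \right]}
#' Used as the independent oracle for the full numeric pipeline on
#' isotropic-rotor fixtures.
#'
#' @param r internuclear distance in nm.
#' @param tau_c rotational correlation time in ps.
#' @param B0 field strength in tesla.
#' @return rate in Hz.
#' @export
bpp_r1 <- function(r, tau_c, B0) {
  w <- field_spec(B0)$omega_L           # rad/s
  tc <- tau_c * 1e-12                   # s
  r_m <- r * 1e-9
  (3 / 10) * dipolar_prefactor()^2 * r_m^-6 *
    (tc / (1 + w^2 * tc^2) + 4 * tc / (1 + 4 * w^2 * tc^2))
}
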