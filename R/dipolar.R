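#' Polar coordinate series of an internuclear vector
#'
#' Converts the relative position of nucleus `j` with respect to nucleus
#' `i` into polar coordinates `(r, theta, phi)` for every frame. The main
#' magnetic field defines the z-axis, so `theta` is the angle between the
#' internuclear vector and B0. When the trajectory is periodic the
#' relative vector is taken under the minimum-image convention.
#'
#' @param traj a [spin_trajectory()].
#' @param i,j nucleus indices (i != j).
#' @return object of class `polar_series`: list with numeric vectors `r`
#'   (nm), `theta` (rad, in `[0, pi]`), `phi` (rad, in `(-pi, pi]`) and
#'   `dt` (ps).
#' @export
pair_polar_series <- function(traj, i, j) {
  stopifnot(inherits(traj, "spin_trajectory"))
  if (i == j) stop("i and j must differ")
  d <- traj$coords[, j, , drop = FALSE] - traj$coords[, i, , drop = FALSE]
  d <- array(d, dim(d)[c(1, 3)])
  if (!is.null(traj$box))
    for (ax in 1:3)
      d[, ax] <- d[, ax] - traj$box[ax] * round(d[, ax] / traj$box[ax])
  r <- sqrt(rowSums(d^2))
  if (any(r < 1e-12))
    stop("coincident nuclei ", i, " and ", j, " in frame ",
         which(r < 1e-12)[1])
  structure(list(r = r,
                 theta = acos(pmin(1, pmax(-1, d[, 3] / r))),
                 phi = atan2(d[, 2], d[, 1]),
                 dt = traj$dt),
            class = "polar_series")
}

#' Second-rank spherical harmonic series of a spin pair
#'
#' Evaluates the rank-2 dipolar spherical harmonics
#' \deqn{F_{2,0} = (1 - 3\cos^2\theta)/r^3,\quad
#'       F_{2,1} = \sin\theta\cos\theta\, e^{-i\phi}/r^3,\quad
#'       F_{2,2} = \sin^2\theta\, e^{-2i\phi}/r^3}
#' for each frame. Only `q >= 0` is stored since
#' \eqn{F_{2,-q} = F_{2,q}^*}.
#'
#' @param p a [pair_polar_series()] result.
#' @return object of class `harmonic_series`: complex vectors `F0`, `F1`,
#'   `F2` in nm^-3 plus `dt` (ps).
#' @export
harmonics_from_polar <- function(p) {
  stopifnot(inherits(p, "polar_series"))
  r3 <- p$r^3
  ct <- cos(p$theta); st <- sin(p$theta)
  structure(list(
    F0 = as.complex((1 - 3 * ct^2) / r3),
    F1 = st * ct * exp(-1i * p$phi) / r3,
    F2 = st^2 * exp(-2i * p$phi) / r3,
    dt = p$dt), class = "harmonic_series")
}

#' Lag autocorrelation functions of a harmonic series
#'
#' Computes \eqn{G_q(\tau) = \mathrm{Re}\langle F_q(t) F_q^*(t+\tau)
#' \rangle_t} for q = 0, 1, 2 with the unbiased per-lag divisor (number of
#' contributing time origins), using FFTs zero-padded to at least twice
#' the series length to avoid circular wrap-around. The lag grid is
#' truncated at `truncation_fraction` of the series duration because the
#' tail of a finite-trajectory correlation estimate is dominated by noise.
#'
#' @param h a [harmonics_from_polar()] result.
#' @param truncation_fraction fraction of the duration to keep, in
#'   `(0, 1]`; default 0.3.
#' @return object of class `correlation_fn`: `lags` (ps), matrix `G`
#'   (nm^-6, columns `q0`, `q1`, `q2`), magnitudes `A = G(0)`, `dt`,
#'   `normalized = FALSE`.
#' @export
autocorrelate <- function(h, truncation_fraction = 0.3) {
  stopifnot(inherits(h, "harmonic_series"))
  if (truncation_fraction <= 0 || truncation_fraction > 1)
    stop("truncation_fraction must be in (0, 1]")
  n <- length(h$F0)
  if (n < 10) stop("series too short to autocorrelate (need >= 10 frames)")
  n_lag <- max(2L, floor(truncation_fraction * (n - 1)) + 1L)
  M <- 2^ceiling(log2(n + n_lag))
  acf_fft <- function(x) {
    X <- stats::fft(c(x, rep(0 + 0i, M - n)))
    s <- stats::fft(X * Conj(X), inverse = TRUE) / M
    Re(s[seq_len(n_lag)]) / (n - seq_len(n_lag) + 1L)
  }
  G <- cbind(q0 = acf_fft(h$F0), q1 = acf_fft(h$F1), q2 = acf_fft(h$F2))
  structure(list(lags = (seq_len(n_lag) - 1L) * h$dt, G = G,
                 A = G[1, ], dt = h$dt, normalized = FALSE,
                 truncation_fraction = truncation_fraction),
            class = "correlation_fn")
}

#' Sum correlation functions over partner nuclei
#'
#' Per-proton dipolar rates sum pairwise spectral densities over partner
#' nuclei; since integration is linear this equals the spectral density of
#' the lag-wise sum of the pairwise correlation functions.
#'
#' @param cfs list of `correlation_fn` objects on identical lag grids.
#' @return a `correlation_fn` holding the sum.
#' @export
sum_correlations <- function(cfs) {
  stopifnot(length(cfs) >= 1)
  out <- cfs[[1]]
  if (length(cfs) > 1) for (k in 2:length(cfs)) {
    if (length(cfs[[k]]$lags) != length(out$lags))
      stop("correlation functions have different lag grids")
    out$G <- out$G + cfs[[k]]$G
  }
  out$A <- out$G[1, ]
  out
}

#' Numerically integrated spectral density
#'
#' Evaluates \eqn{J_q(\omega) = 2\int_0^{\tau_{max}} G_q(\tau)
#' \cos(\omega\tau)\, d\tau} by the trapezoidal rule on the truncated lag
#' grid. No tail extrapolation beyond the last lag is applied; slowly
#' decaying (macromolecular) correlations should go through the
#' model-free route instead.
#'
#' @param cf an (unnormalized) [autocorrelate()] result.
#' @param omega angular frequencies in rad/s (vector).
#' @return object of class `spectral_density`: data.frame with columns
#'   `omega` (rad/s), `J0`, `J1`, `J2` in nm^-6 ps (`units` attribute
#'   `"nm^-6.ps"`); convert with [as_si_J()] before rate assembly.
#' @export
spectral_density_numeric <- function(cf, omega) {
  stopifnot(inherits(cf, "correlation_fn"))
  if (isTRUE(cf$normalized))
    stop("spectral_density_numeric needs absolute (unnormalized) G; ",
         "supply magnitudes separately or skip normalize()")
  dt_s <- cf$dt * 1e-12
  if (any(abs(omega) * dt_s > pi / 4))
    stop("omega*dt exceeds pi/4: the lag grid cannot resolve the ",
         "cosine oscillation; decrease dt")
  w_ps <- abs(omega) * 1e-12            # rad/s -> rad/ps; J is even in omega
  tau <- cf$lags
  n <- length(tau)
  trapz_w <- c(diff(tau) / 2, 0) + c(0, diff(tau) / 2)
  J <- vapply(w_ps, function(w) {
    cw <- cos(w * tau) * trapz_w
    2 * colSums(cf$G * cw)
  }, numeric(3))
  out <- data.frame(omega = omega, J0 = J[1, ], J1 = J[2, ], J2 = J[3, ])
  attr(out, "units") <- "nm^-6.ps"
  attr(out, "method") <- "numeric"
  class(out) <- c("spectral_density", class(out))
  out
}

#' Export a correlation function to CSV
#' @param cf a `correlation_fn`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_correlation_csv <- function(cf, path) {
  utils::write.csv(data.frame(lag_ps = cf$lags, cf$G), path,
                   row.names = FALSE)
  invisible(path)
}
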