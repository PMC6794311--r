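#' Physical constants and field specification
#'
#' Dipolar relaxation rates depend on three physical constants: the vacuum
#' permeability (through \eqn{\mu_0/4\pi}), the proton gyromagnetic ratio
#' \eqn{\gamma_H} and the reduced Planck constant \eqn{\hbar}. They enter
#' every rate expression only through the dipolar coupling prefactor
#' \eqn{K = (\mu_0/4\pi)\,\gamma_H^2\,\hbar} (SI units, m^3/s when
#' multiplied by r^-3).
#'
#' @name spinrelax-constants
#' @keywords internal
NULL

## CODATA values, SI
.const <- list(
  gamma_H     = 2.6752218744e8,   # rad s^-1 T^-1
  hbar        = 1.054571817e-34,  # J s
  mu0_over_4pi = 1e-7             # T m A^-1
)

#' Dipolar coupling prefactor K
#'
#' \eqn{K = (\mu_0/4\pi)\gamma_H^2\hbar} in SI units. The intra-pool rate
#' prefactor is \eqn{(9/8)K^2}, the auto/cross-relaxation prefactor
#' \eqn{(1/16)K^2}.
#'
#' @return K in m^3 s^-1 (i.e. \eqn{K r^{-3}} is an angular frequency).
#' @export
#' @examples
#' dipolar_prefactor() # ~7.55e-25
dipolar_prefactor <- function() {
  .const$mu0_over_4pi * .const$gamma_H^2 * .const$hbar
}

#' Magnetic field specification
#'
#' Bundles a static field strength B0 with the proton Larmor angular
#' frequency \eqn{\omega_L = \gamma_H B_0}.
#'
#' @param B0 field strength in tesla (> 0).
#' @return object of class `field_spec` with elements `B0` (T) and
#'   `omega_L` (rad/s).
#' @export
#' @examples
#' field_spec(3)$omega_L / (2 * pi) / 1e6 # ~127.7 MHz
field_spec <- function(B0) {
  if (!is.numeric(B0) || length(B0) != 1L || !is.finite(B0) || B0 <= 0)
    stop("B0 must be a single positive number (tesla)")
  structure(list(B0 = B0, omega_L = .const$gamma_H * B0),
            class = "field_spec")
}

#' @export
print.field_spec <- function(x, ...) {
  cat(sprintf("field_spec: B0 = %g T, omega_L = %.6g rad/s (%.2f MHz)\n",
              x$B0, x$omega_L, x$omega_L / (2 * pi) / 1e6))
  invisible(x)
}

## Spectral densities are computed on the trajectory's native scale
## (nm^-6 ps) and converted to SI (m^-6 s) exactly once, at rate assembly:
## nm^-6 -> m^-6 is 1e54, ps -> s is 1e-12.
.J_NM_PS_TO_SI <- 1e42

#' Convert spectral density values to SI units
#'
#' Tags the result so that the rate-assembly functions can refuse spectral
#' densities on the wrong scale (passing nm-based J into an SI prefactor is
#' a silent factor-1e42 bug otherwise).
#'
#' @param J numeric, spectral density in nm^-6 ps.
#' @return numeric in m^-6 s, carrying `units` attribute `"m^-6.s"`.
#' @export
as_si_J <- function(J) {
  u <- attr(J, "units")
  if (!is.null(u) && identical(u, "m^-6.s"))
    return(J)
  out <- unclass(J) * .J_NM_PS_TO_SI
  attr(out, "units") <- "m^-6.s"
  out
}

.assert_si_J <- function(J, arg = deparse(substitute(J))) {
  if (!identical(attr(J, "units"), "m^-6.s"))
    stop(sprintf(
      "%s must be an SI spectral density (m^-6 s); use as_si_J() on values in nm^-6 ps",
      arg))
  invisible(TRUE)
}
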