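#' Normalize a correlation function
#'
#' Divides each `G_q` by its zero-lag magnitude so that
#' `Ghat_q(0) = 1`; the magnitudes `A_q` are retained for rescaling the
#' model-free spectral densities. Normalizing twice is a no-op.
#'
#' @param cf a `correlation_fn` from [autocorrelate()].
#' @return normalized `correlation_fn` (magnitudes kept in `$A`).
#' @export
normalize_correlation <- function(cf) {
  stopifnot(inherits(cf, "correlation_fn"))
  if (isTRUE(cf$normalized)) return(cf)
  if (any(cf$A <= 0))
    stop("G_q(0) must be positive to normalize (no dipolar coupling in q = ",
         paste(which(cf$A <= 0) - 1, collapse = ", "), ")")
  cf$G <- sweep(cf$G, 2, cf$A, "/")
  cf$normalized <- TRUE
  cf
}

#' Fit the two-timescale model-free form to a normalized correlation
#'
#' Fits \deqn{\hat G(\tau) = S^2 e^{-\tau/\tau_M} +
#' (1 - S^2) e^{-\tau/\tau_i}} by bounded Levenberg-Marquardt least
#' squares with `S2` in `[0, 1]`, `tau_i <= tau_M` and both times in
#' `[dt, 100 tau_max]`. A multi-start grid over `S2` and `tau_M` guards
#' against local minima; the best-residual attempt is returned. Each
#' harmonic order q is fitted independently. When the fitted fast
#' amplitude `1 - S2` is below 0.01, `tau_i` is not identifiable from the
#' data and is flagged as such.
#'
#' @param cf a normalized `correlation_fn` (or one that will be
#'   normalized on the fly), with at least 20 lag points.
#' @param q which harmonic orders to fit, subset of `c("q0","q1","q2")`.
#' @return object of class `modelfree_fits`: named list of per-q
#'   `modelfree_fit` objects with fields `S2`, `tau_M`, `tau_i` (ps),
#'   `A_q` (nm^-6), `residual` (SSR), `converged`,
#'   `tau_i_identifiable`.
#' @export
fit_modelfree <- function(cf, q = c("q0", "q1", "q2")) {
  stopifnot(inherits(cf, "correlation_fn"))
  q <- match.arg(q, several.ok = TRUE)
  if (length(cf$lags) < 20)
    stop("need at least 20 lag points for a model-free fit")
  cfn <- normalize_correlation(cf)
  fits <- lapply(q, function(qq)
    .fit_mf_single(cfn$lags, cfn$G[, qq], cfn$A[[qq]], cfn$dt))
  names(fits) <- q
  structure(fits, class = "modelfree_fits")
}

.fit_mf_single <- function(tau, ghat, A_q, dt) {
  if (any(!is.finite(ghat))) stop("non-finite correlation values")
  tau_max <- max(tau)
  # a dense uniform lag grid over-weights the noisy long-lag region in a
  # multi-exponential fit; subsample log-spaced across lag decades
  if (length(tau) > 600) {
    keep <- unique(c(1L, round(exp(seq(log(2), log(length(tau)),
                                       length.out = 600)))))
    tau <- tau[keep]; ghat <- ghat[keep]
  }
  lower <- c(S2 = 0, tau_M = dt, tau_i = dt)
  upper <- c(S2 = 1, tau_M = 100 * tau_max, tau_i = 100 * tau_max)
  # tau_i guess from the initial 10% decay: Ghat(t) ~ exp(-t/tau) there
  head_idx <- which(tau <= 0.1 * tau_max & ghat > 0)
  tau_i0 <- if (length(head_idx) > 3) {
    sl <- stats::coef(stats::lm(log(ghat[head_idx]) ~ tau[head_idx]))[2]
    if (is.finite(sl) && sl < 0) min(max(-1 / sl, dt), tau_max) else
      0.05 * tau_max
  } else 0.05 * tau_max
  starts <- expand.grid(S2 = c(0.2, 0.5, 0.8),
                        tau_M = c(0.1, 1, 10) * 0.1 * tau_max,
                        tau_i = tau_i0)
  # informed start: plateau height after the fast decay, slow time from
  # the log-slope of the tail
  mid <- which(tau >= 3 * tau_i0 & tau <= 0.5 * tau_max & ghat > 0)
  if (length(mid) > 5) {
    sl <- stats::coef(stats::lm(log(ghat[mid]) ~ tau[mid]))
    if (is.finite(sl[2]) && sl[2] < 0)
      starts <- rbind(starts, data.frame(
        S2 = min(0.99, max(0.01, exp(sl[1]))),
        tau_M = min(max(-1 / sl[2], dt), 100 * tau_max),
        tau_i = tau_i0))
  }
  resid_fn <- function(p)
    ghat - (p[1] * exp(-tau / p[2]) + (1 - p[1]) * exp(-tau / p[3]))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    p0 <- c(S2 = starts$S2[s], tau_M = starts$tau_M[s],
            tau_i = min(starts$tau_i[s], starts$tau_M[s]))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, maxfev = 10000,
                           ptol = 1e-10, ftol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr)
      best <- list(ssr = ssr, coef = fit$par,
                   # info 1-4: gradient/step criteria met; 6-7: no
                   # further improvement possible at this tolerance
                   converged = fit$info %in% c(1:4, 6, 7))
  }
  if (is.null(best))
    return(structure(list(S2 = NA_real_, tau_M = NA_real_,
                          tau_i = NA_real_, A_q = A_q,
                          residual = NA_real_, converged = FALSE,
                          tau_i_identifiable = FALSE),
                     class = "modelfree_fit"))
  co <- best$coef
  # the form is symmetric under (S2, tau_M) <-> (1-S2, tau_i); order so
  # that tau_M is the slow time
  if (co[["tau_i"]] > co[["tau_M"]])
    co <- c(S2 = 1 - co[["S2"]], tau_M = co[["tau_i"]],
            tau_i = co[["tau_M"]])
  # when both times coincide the split is unidentifiable: report the
  # amplitude-weighted single time as the S2 = 1 corner
  if (co[["tau_i"]] > 0.99 * co[["tau_M"]]) {
    tau_eff <- co[["S2"]] * co[["tau_M"]] + (1 - co[["S2"]]) * co[["tau_i"]]
    co <- c(S2 = 1, tau_M = tau_eff, tau_i = tau_eff)
  }
  structure(list(S2 = unname(co[["S2"]]), tau_M = unname(co[["tau_M"]]),
                 tau_i = unname(co[["tau_i"]]), A_q = A_q,
                 residual = best$ssr, converged = isTRUE(best$converged),
                 tau_i_identifiable = (1 - co[["S2"]]) >= 0.01),
            class = "modelfree_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.modelfree_fit <- function(x, ...) {
  cat(sprintf(
    "model-free fit: S2 = %.4f, tau_M = %.4g ps, tau_i = %.4g ps%s (SSR %.3g)\n",
    x$S2, x$tau_M, x$tau_i,
    if (!x$tau_i_identifiable) " [tau_i unidentifiable]" else "",
    x$residual))
  invisible(x)
}

#' Closed-form model-free spectral density
#'
#' Evaluates \deqn{J(\omega) = 2 A_q \left\{ \frac{S^2\tau_M}
#' {1 + \omega^2\tau_M^2} + \frac{(1-S^2)\tau_i}{1 + \omega^2\tau_i^2}
#' \right\}} for a fitted parameter set. The result is on the
#' trajectory's native scale (nm^-6 ps) like the numeric route.
#'
#' @param fit a single `modelfree_fit` (one element of
#'   [fit_modelfree()]'s result).
#' @param omega angular frequencies in rad/s.
#' @param override evaluate even if the fit did not converge.
#' @return numeric vector of J values in nm^-6 ps (with `units`
#'   attribute), same length as `omega`.
#' @export
spectral_density_modelfree <- function(fit, omega, override = FALSE) {
  stopifnot(inherits(fit, "modelfree_fit"))
  if (!fit$converged && !override)
    stop("fit did not converge; pass override = TRUE to evaluate anyway")
  w <- abs(omega) * 1e-12               # rad/s -> rad/ps
  J <- 2 * fit$A_q * (fit$S2 * fit$tau_M / (1 + w^2 * fit$tau_M^2) +
                        (1 - fit$S2) * fit$tau_i / (1 + w^2 * fit$tau_i^2))
  attr(J, "units") <- "nm^-6.ps"
  J
}
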