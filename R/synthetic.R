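#' Motion specification for the synthetic trajectory generators
#'
#' The generators produce hydrogen trajectories with *known* motional
#' parameters so that every downstream stage (harmonics, correlation
#' functions, spectral densities, rates) can be validated against an
#' analytic or recorded ground truth. Four kinds of motion are available:
#'
#' * `isotropic_rotor`: rigid two-proton units whose orientation performs
#'   free rotational Brownian motion with rotational correlation time
#'   `tau_c` (the rank-2 orientational correlation decays as
#'   `exp(-tau/tau_c)` with `tau_c = 1/(6 D_r)`).
#' * `cone_restricted_rotor`: wobble-in-a-cone internal motion (order
#'   parameter `S2_target`, internal time `tau_i`) superimposed on global
#'   isotropic tumbling at `tau_M`; the normalized rank-2 correlation
#'   approximates `S2 exp(-tau/tau_M) + (1-S2) exp(-tau/tau_eff)`.
#' * `translational_brownian`: free 3D Brownian paths with diffusion
#'   coefficient `D`.
#' * `water_slab`: rigid H-H pairs diffusing between reflecting walls with
#'   position-dependent mobility `mobility_profile(z)`, emulating the
#'   reduced water mobility near a membrane surface.
#'
#' @param kind one of `"isotropic_rotor"`, `"cone_restricted_rotor"`,
#'   `"translational_brownian"`, `"water_slab"`.
#' @param dt sampling interval in ps.
#' @param n_steps number of frames.
#' @param seed master seed; all stochastic draws derive from it.
#' @param tau_c rotational correlation time in ps (isotropic rotor).
#' @param S2_target order parameter in `[0, 1]` (cone rotor).
#' @param tau_M global correlation time in ps (cone rotor).
#' @param tau_i internal correlation time in ps (cone rotor; must be
#'   `< tau_M`).
#' @param D translational diffusion coefficient in cm^2/s.
#' @param pair_distance intra-pair H-H distance in nm.
#' @param slab_width slab extent in z, nm (water slab).
#' @param mobility_profile list with functions `tau_c(z)` (ps) and `D(z)`
#'   (cm^2/s) of the slab coordinate z (water slab).
#' @param n_pairs,n_molecules number of units.
#' @return object of class `motion_spec`.
#' @export
motion_spec <- function(kind, dt, n_steps, seed = 1L,
                        tau_c = NULL, S2_target = NULL, tau_M = NULL,
                        tau_i = NULL, D = NULL,
                        pair_distance = 0.158, slab_width = NULL,
                        mobility_profile = NULL,
                        n_pairs = 1L, n_molecules = 1L) {
  kind <- match.arg(kind, c("isotropic_rotor", "cone_restricted_rotor",
                            "translational_brownian", "water_slab"))
  if (dt <= 0 || n_steps < 1) stop("dt must be > 0 and n_steps >= 1")
  if (pair_distance <= 0) stop("pair_distance must be > 0")
  if (kind == "isotropic_rotor" && (is.null(tau_c) || tau_c <= 0))
    stop("isotropic_rotor requires tau_c > 0")
  if (kind == "cone_restricted_rotor") {
    if (is.null(S2_target) || S2_target <= 0 || S2_target > 1)
      stop("cone_restricted_rotor requires S2_target in (0, 1]; ",
           "use isotropic_rotor for the S2 = 0 limit")
    if (is.null(tau_M) || tau_M <= 0 || is.null(tau_i) || tau_i <= 0)
      stop("cone_restricted_rotor requires tau_M > 0 and tau_i > 0")
    if (tau_i >= tau_M)
      stop("timescale separation requires tau_i < tau_M")
  }
  if (kind %in% c("translational_brownian", "water_slab")) {
    if (is.null(D) && kind == "translational_brownian")
      stop("translational_brownian requires D")
    if (!is.null(D) && D < 0) stop("D must be >= 0")
  }
  if (kind == "water_slab") {
    if (is.null(slab_width) || slab_width <= 0)
      stop("water_slab requires slab_width > 0")
    if (is.null(mobility_profile) ||
        !is.function(mobility_profile$tau_c) ||
        !is.function(mobility_profile$D))
      stop("water_slab requires mobility_profile with functions tau_c(z) and D(z)")
  }
  structure(list(kind = kind, dt = dt, n_steps = as.integer(n_steps),
                 seed = as.integer(seed), tau_c = tau_c,
                 S2_target = S2_target, tau_M = tau_M, tau_i = tau_i,
                 D = D, pair_distance = pair_distance,
                 slab_width = slab_width,
                 mobility_profile = mobility_profile,
                 n_pairs = as.integer(n_pairs),
                 n_molecules = as.integer(n_molecules)),
            class = "motion_spec")
}

## evaluate expr with a locally seeded RNG, restoring global RNG state
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv())
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

## Rodrigues rotation of the rows of u (n x 3 unit vectors) by rotation
## vectors w (n x 3); |w| is the angle, w/|w| the axis
.rotate_rows <- function(u, w) {
  alpha <- sqrt(rowSums(w^2))
  ok <- alpha > 0
  if (!any(ok)) return(u)
  k <- w
  k[ok, ] <- w[ok, ] / alpha[ok]
  ca <- cos(alpha); sa <- sin(alpha)
  kxu <- cbind(k[, 2] * u[, 3] - k[, 3] * u[, 2],
               k[, 3] * u[, 1] - k[, 1] * u[, 3],
               k[, 1] * u[, 2] - k[, 2] * u[, 1])
  kdu <- rowSums(k * u)
  out <- u * ca + kxu * sa + k * (kdu * (1 - ca))
  out[!ok, ] <- u[!ok, , drop = FALSE]
  out / sqrt(rowSums(out^2))
}

.runif_sphere <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  cbind(s * cos(phi), s * sin(phi), z)
}

.check_rot_step <- function(dt, tau, what) {
  # per-axis angular step variance 2 D_r dt = dt/(3 tau)
  if (dt / (3 * tau) > 0.1)
    stop(sprintf(
      "dt = %g ps too large relative to %s = %g ps (angular step variance %.3g rad^2 > 0.1); the discretized rotation would bias the correlation decay",
      dt, what, tau, dt / (3 * tau)))
}

## assemble pair trajectories: centers (n_pairs x 3 or array) and
## orientations U (n_steps x n_pairs x 3) -> coords for 2*n_pairs atoms
.pair_coords <- function(centers, U, d) {
  nf <- dim(U)[1]; np <- dim(U)[2]
  coords <- array(NA_real_, c(nf, 2L * np, 3L))
  half <- d / 2
  cent <- if (length(dim(centers)) == 3L) centers else
    aperm(array(rep(t(centers), nf), c(3, np, nf)), c(3, 2, 1))
  coords[, seq(1, 2 * np, by = 2), ] <- cent + half * U
  coords[, seq(2, 2 * np, by = 2), ] <- cent - half * U
  coords
}

#' Generate isotropically tumbling spin pairs
#'
#' Rigid two-proton units with fixed internuclear distance whose
#' orientation performs free rotational Brownian motion: each step applies
#' a small random rotation with per-axis angular variance `2 D_r dt`,
#' `D_r = 1/(6 tau_c)`. The stationary orientation distribution is uniform
#' on the sphere and the rank-2 orientational correlation decays as
#' `exp(-tau/tau_c)`. Pair centres are fixed on a sparse 10 nm grid so
#' inter-pair dipolar couplings are negligible (`r^-6` suppression of
#' ~1e-11 relative to the intra-pair term).
#'
#' @param spec a [motion_spec()] with `kind = "isotropic_rotor"`.
#' @return a [spin_trajectory()] with ground truth recorded in
#'   `metadata`.
#' @export
generate_isotropic_rotor <- function(spec) {
  stopifnot(inherits(spec, "motion_spec"), spec$kind == "isotropic_rotor")
  np <- spec$n_pairs; nf <- spec$n_steps
  if (nf > 1L) .check_rot_step(spec$dt, spec$tau_c, "tau_c")
  sdw <- sqrt(2 * (1 / (6 * spec$tau_c)) * spec$dt)
  U <- .with_seed(spec$seed, {
    u <- .runif_sphere(np)
    out <- array(NA_real_, c(nf, np, 3))
    out[1, , ] <- u
    if (nf > 1L) for (f in 2:nf) {
      u <- .rotate_rows(u, matrix(stats::rnorm(3 * np, 0, sdw), np, 3))
      out[f, , ] <- u
    }
    out
  })
  centers <- cbind(10 * (seq_len(np) - 1), 0, 0)
  spin_trajectory(.pair_coords(centers, U, spec$pair_distance), spec$dt,
                  species = rep("ROT", 2 * np),
                  molecule_id = rep(seq_len(np), each = 2),
                  pool = rep("WP", 2 * np),
                  metadata = list(kind = "isotropic_rotor",
                                  tau_c = spec$tau_c,
                                  pair_distance = spec$pair_distance,
                                  seed = spec$seed))
}

#' Cone half-angle for a target order parameter
#'
#' For uniform wobble in a cone of half-angle `beta`, the order parameter
#' is `S = cos(beta) (1 + cos(beta)) / 2` and `S2 = S^2`. This inverts
#' that relation.
#'
#' @param S2 target squared order parameter in (0, 1].
#' @return cone half-angle in rad.
#' @export
cone_half_angle <- function(S2) {
  if (S2 <= 0 || S2 > 1) stop("S2 must be in (0, 1]")
  if (S2 == 1) return(0)
  S <- sqrt(S2)
  stats::uniroot(function(b) cos(b) * (1 + cos(b)) / 2 - S,
                 c(1e-9, pi - 1e-9), tol = 1e-12)$root
}

#' Generate cone-restricted rotors
#'
#' Wobble-in-a-cone internal motion superimposed on global isotropic
#' tumbling. The cone half-angle is chosen so the cone order parameter
#' `[cos(beta)(1+cos(beta))/2]^2` equals `S2_target`; the internal wobble
#' is a reflected rotational diffusion inside the cone with nominal time
#' constant `tau_i`, while the cone axis (and the pair vector with it)
#' tumbles isotropically with correlation time `tau_M`. The normalized
#' rank-2 correlation then approximates the two-exponential form
#' `S2 exp(-tau/tau_M) + (1-S2) exp(-tau/tau_eff)`. `S2_target = 1`
#' degenerates to a pure global rotor.
#'
#' @param spec a [motion_spec()] with `kind = "cone_restricted_rotor"`.
#' @return a [spin_trajectory()]; ground truth `(S2, tau_M, tau_i)` in
#'   `metadata`.
#' @export
generate_cone_restricted_rotor <- function(spec) {
  stopifnot(inherits(spec, "motion_spec"),
            spec$kind == "cone_restricted_rotor")
  np <- spec$n_pairs; nf <- spec$n_steps
  .check_rot_step(spec$dt, spec$tau_M, "tau_M")
  if (spec$S2_target < 1) .check_rot_step(spec$dt, spec$tau_i, "tau_i")
  beta <- cone_half_angle(spec$S2_target)
  sdM <- sqrt(2 * (1 / (6 * spec$tau_M)) * spec$dt)
  sdI <- sqrt(2 * (1 / (6 * spec$tau_i)) * spec$dt)
  U <- .with_seed(spec$seed, {
    a <- .runif_sphere(np)             # cone axes
    u <- a
    if (beta > 0) {                    # start uniform inside the cone
      cb <- stats::runif(np, cos(beta), 1)
      sb <- sqrt(1 - cb^2)
      ph <- stats::runif(np, 0, 2 * pi)
      # orthonormal frame around each axis
      ref <- cbind(rep(1, np), 0, 0)
      swap <- abs(a[, 1]) > 0.9
      ref[swap, ] <- matrix(rep(c(0, 1, 0), sum(swap)), ncol = 3,
                            byrow = TRUE)
      e1 <- cbind(a[, 2] * ref[, 3] - a[, 3] * ref[, 2],
                  a[, 3] * ref[, 1] - a[, 1] * ref[, 3],
                  a[, 1] * ref[, 2] - a[, 2] * ref[, 1])
      e1 <- e1 / sqrt(rowSums(e1^2))
      e2 <- cbind(a[, 2] * e1[, 3] - a[, 3] * e1[, 2],
                  a[, 3] * e1[, 1] - a[, 1] * e1[, 3],
                  a[, 1] * e1[, 2] - a[, 2] * e1[, 1])
      u <- a * cb + e1 * (sb * cos(ph)) + e2 * (sb * sin(ph))
    }
    out <- array(NA_real_, c(nf, np, 3))
    out[1, , ] <- u
    if (nf > 1L) for (f in 2:nf) {
      wg <- matrix(stats::rnorm(3 * np, 0, sdM), np, 3)
      a <- .rotate_rows(a, wg)         # global tumbling carries the cone
      u <- .rotate_rows(u, wg)
      if (beta > 0) {                  # internal wobble, reflected at beta
        u <- .rotate_rows(u, matrix(stats::rnorm(3 * np, 0, sdI), np, 3))
        cth <- pmin(1, pmax(-1, rowSums(u * a)))
        th <- acos(cth)
        out_of_cone <- th > beta
        if (any(out_of_cone)) {
          i <- which(out_of_cone)
          ax <- cbind(u[i, 2] * a[i, 3] - u[i, 3] * a[i, 2],
                      u[i, 3] * a[i, 1] - u[i, 1] * a[i, 3],
                      u[i, 1] * a[i, 2] - u[i, 2] * a[i, 1])
          nrm <- sqrt(rowSums(ax^2))
          good <- nrm > 1e-12
          ang <- 2 * pmin(th[i] - beta, beta)  # reflect, clamp into cone
          w <- matrix(0, length(i), 3)
          w[good, ] <- ax[good, , drop = FALSE] / nrm[good] * ang[good]
          u[i, ] <- .rotate_rows(u[i, , drop = FALSE], w)
        }
      }
      out[f, , ] <- u
    }
    out
  })
  centers <- cbind(10 * (seq_len(np) - 1), 0, 0)
  spin_trajectory(.pair_coords(centers, U, spec$pair_distance), spec$dt,
                  species = rep("MAC", 2 * np),
                  molecule_id = rep(seq_len(np), each = 2),
                  pool = rep("MP", 2 * np),
                  metadata = list(kind = "cone_restricted_rotor",
                                  S2 = spec$S2_target, tau_M = spec$tau_M,
                                  tau_i = spec$tau_i, beta = beta,
                                  pair_distance = spec$pair_distance,
                                  seed = spec$seed))
}

#' Generate free translational Brownian motion
#'
#' 3D Brownian paths with per-step displacement variance `2 D dt` per
#' axis. Each molecule carries a single hydrogen marker; use
#' [estimate_diffusion()] to recover `D` from the mean square
#' displacement (Einstein relation `MSD = 6 D t`).
#'
#' @param spec a [motion_spec()] with `kind = "translational_brownian"`;
#'   `D` in cm^2/s.
#' @return a [spin_trajectory()].
#' @export
generate_translational_brownian <- function(spec) {
  stopifnot(inherits(spec, "motion_spec"),
            spec$kind == "translational_brownian")
  n <- spec$n_molecules; nf <- spec$n_steps
  D_nm <- spec$D * 100                  # cm^2/s -> nm^2/ps
  sd_step <- sqrt(2 * D_nm * spec$dt)
  coords <- .with_seed(spec$seed, {
    out <- array(0, c(nf, n, 3))
    if (nf > 1L && sd_step > 0) {
      for (ax in 1:3) {
        inc <- matrix(stats::rnorm((nf - 1) * n, 0, sd_step), nf - 1, n)
        out[, , ax] <- rbind(0, apply(inc, 2, cumsum))
      }
    }
    out
  })
  spin_trajectory(coords, spec$dt, species = rep("TRN", n),
                  molecule_id = seq_len(n), pool = rep("WP", n),
                  metadata = list(kind = "translational_brownian",
                                  D = spec$D, seed = spec$seed))
}

#' Generate a water slab with position-dependent mobility
#'
#' Point molecules carrying a rigid H-H pair diffuse between reflecting
#' walls at `z = 0` and `z = slab_width` with locally varying diffusion
#' coefficient `D(z)`, while the pair orientation tumbles with locally
#' varying correlation time `tau_c(z)`. A profile that slows down near the
#' walls emulates the reduced water mobility near a membrane surface and
#' produces the corresponding parabola-like R1 relaxation profile.
#'
#' @param spec a [motion_spec()] with `kind = "water_slab"`.
#' @return a [spin_trajectory()]; the mobility profile is stored in
#'   `metadata` for recovery tests.
#' @export
generate_water_slab <- function(spec) {
  stopifnot(inherits(spec, "motion_spec"), spec$kind == "water_slab")
  n <- spec$n_molecules; nf <- spec$n_steps; W <- spec$slab_width
  prof <- spec$mobility_profile
  zg <- seq(0, W, length.out = 101)
  tc <- prof$tau_c(zg); Dg <- prof$D(zg)
  if (any(!is.finite(tc)) || any(tc <= 0) ||
      any(!is.finite(Dg)) || any(Dg <= 0))
    stop("mobility_profile must be finite and positive on [0, slab_width]")
  .check_rot_step(spec$dt, min(tc), "min tau_c(z)")
  d <- spec$pair_distance
  res <- .with_seed(spec$seed, {
    pos <- cbind(stats::runif(n, 0, W), stats::runif(n, 0, W),
                 stats::runif(n, 0, W))
    u <- .runif_sphere(n)
    cent <- array(NA_real_, c(nf, n, 3))
    U <- array(NA_real_, c(nf, n, 3))
    cent[1, , ] <- pos
    U[1, , ] <- u
    if (nf > 1L) for (f in 2:nf) {
      z <- pos[, 3]
      D_nm <- prof$D(z) * 100
      sd_t <- sqrt(2 * D_nm * spec$dt)
      pos <- pos + matrix(stats::rnorm(3 * n), n, 3) * sd_t
      # reflecting walls in z
      z <- pos[, 3]
      repeat {
        below <- z < 0; above <- z > W
        if (!any(below) && !any(above)) break
        z[below] <- -z[below]
        z[above] <- 2 * W - z[above]
      }
      pos[, 3] <- z
      sd_r <- sqrt(2 * spec$dt / (6 * prof$tau_c(z)))
      u <- .rotate_rows(u, matrix(stats::rnorm(3 * n), n, 3) * sd_r)
      cent[f, , ] <- pos
      U[f, , ] <- u
    }
    list(cent = cent, U = U)
  })
  spin_trajectory(.pair_coords(res$cent, res$U, d), spec$dt,
                  species = rep("SOL", 2 * n),
                  molecule_id = rep(seq_len(n), each = 2),
                  pool = rep("WP", 2 * n),
                  metadata = list(kind = "water_slab", slab_width = W,
                                  mobility_profile = prof,
                                  pair_distance = d, seed = spec$seed))
}

#' Mean square displacement and diffusion coefficient estimate
#'
#' Computes the molecule-centroid mean square displacement over a set of
#' lag times (averaging over all time origins on a stride) and estimates
#' the diffusion coefficient from the Einstein relation `MSD = 6 D t` by a
#' through-origin least-squares fit.
#'
#' @param traj a [spin_trajectory()].
#' @param max_lag_frames largest lag, in frames; default 10% of the
#'   trajectory.
#' @param n_lags number of lag values (evenly spaced).
#' @param origin_stride use every `origin_stride`-th frame as a time
#'   origin.
#' @return list with `msd` (data.frame `lag_ps`, `msd_nm2`) and `D`
#'   (cm^2/s).
#' @export
estimate_diffusion <- function(traj, max_lag_frames = NULL, n_lags = 20,
                               origin_stride = 1L) {
  stopifnot(inherits(traj, "spin_trajectory"))
  nf <- n_frames(traj)
  if (nf < 3) stop("trajectory too short for MSD analysis")
  if (is.null(max_lag_frames))
    max_lag_frames <- max(2L, floor(0.1 * nf))
  max_lag_frames <- min(max_lag_frames, nf - 1L)
  # molecule centroids
  mols <- unique(traj$molecule_id)
  cent <- array(0, c(nf, length(mols), 3))
  for (k in seq_along(mols)) {
    idx <- which(traj$molecule_id == mols[k])
    if (length(idx) == 1L) cent[, k, ] <- traj$coords[, idx, ]
    else for (ax in 1:3)
      cent[, k, ax] <- rowMeans(traj$coords[, idx, ax, drop = FALSE])
  }
  lags <- unique(pmax(1L, round(seq(1, max_lag_frames,
                                    length.out = min(n_lags,
                                                     max_lag_frames)))))
  msd <- vapply(lags, function(k) {
    orig <- seq(1L, nf - k, by = origin_stride)
    d <- cent[orig + k, , , drop = FALSE] - cent[orig, , , drop = FALSE]
    mean(d^2) * 3              # mean over axes x3 = mean squared norm
  }, 0)
  lag_ps <- lags * traj$dt
  # through-origin slope; D = slope/6, nm^2/ps -> cm^2/s is 1e-2
  slope <- sum(lag_ps * msd) / sum(lag_ps^2)
  list(msd = data.frame(lag_ps = c(0, lag_ps), msd_nm2 = c(0, msd)),
       D = slope / 6 * 1e-2)
}
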