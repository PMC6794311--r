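make_static_pair <- function(offset, box = NULL) {
  co <- array(0, c(12, 2, 3))            # >= 10 frames for autocorrelate
  for (ax in 1:3) co[, 2, ax] <- offset[ax]
  spin_trajectory(co, dt = 1, molecule_id = c(1, 1), box = box)
}

test_that("polar conversion reproduces simple geometries", {
  p <- pair_polar_series(make_static_pair(c(0, 0, 1)), 1, 2)
  expect_equal(p$r[1], 1)
  expect_equal(p$theta[1], 0)
  p <- pair_polar_series(make_static_pair(c(1, 0, 0)), 1, 2)
  expect_equal(p$theta[1], pi / 2)
  expect_equal(p$phi[1], 0)
})

test_that("periodic pairs use the minimum image", {
  tr <- make_static_pair(c(1.8, 0, 0), box = c(2, 2, 2))
  tr$coords[, 1, 1] <- 0.1
  tr$coords[, 2, 1] <- 1.9
  expect_equal(pair_polar_series(tr, 1, 2)$r[1], 0.2, tolerance = 1e-12)
})

test_that("coincident nuclei are reported with the frame", {
  tr <- make_static_pair(c(0, 0, 1))
  tr$coords[3, 2, ] <- tr$coords[3, 1, ]
  expect_error(pair_polar_series(tr, 1, 2), "frame 3")
  expect_error(pair_polar_series(tr, 2, 2), "differ")
})

test_that("harmonics obey their closed forms and r^-3 scaling", {
  p <- pair_polar_series(make_static_pair(c(0, 0, 0.5)), 1, 2)
  h <- harmonics_from_polar(p)
  expect_equal(h$F0[1], as.complex(-2 / 0.5^3))
  expect_equal(Mod(h$F1[1]), 0)
  expect_equal(Mod(h$F2[1]), 0)
  # magic angle: 1 - 3 cos^2(theta) = 0
  d <- c(sin(acos(1 / sqrt(3))), 0, cos(acos(1 / sqrt(3))))
  hm <- harmonics_from_polar(pair_polar_series(make_static_pair(d), 1, 2))
  expect_equal(Mod(hm$F0[1]), 0, tolerance = 1e-14)
  # doubling r divides every magnitude by 8
  u <- c(0.3, -0.2, 0.6)
  h1 <- harmonics_from_polar(pair_polar_series(make_static_pair(u), 1, 2))
  h2 <- harmonics_from_polar(pair_polar_series(make_static_pair(2 * u), 1, 2))
  for (q in c("F0", "F1", "F2"))
    expect_equal(Mod(h1[[q]][1]), 8 * Mod(h2[[q]][1]), tolerance = 1e-12)
})

test_that("autocorrelation of a constant series is flat at |c|^2", {
  h <- structure(list(F0 = rep(3 + 0i, 50), F1 = rep(1 - 2i, 50),
                      F2 = rep(0.5i, 50), dt = 1),
                 class = "harmonic_series")
  cf <- autocorrelate(h, truncation_fraction = 1)
  expect_equal(cf$G[, "q0"], rep(9, length(cf$lags)))
  expect_equal(cf$G[, "q1"], rep(5, length(cf$lags)))
  expect_equal(cf$G[, "q2"], rep(0.25, length(cf$lags)))
})

test_that("FFT autocorrelation equals the direct double-loop sum", {
  set.seed(31)
  for (n in c(64, 101)) {
    x <- complex(real = rnorm(n), imaginary = rnorm(n))
    h <- structure(list(F0 = x, F1 = x * 1i, F2 = rev(x), dt = 0.5),
                   class = "harmonic_series")
    cf <- autocorrelate(h, truncation_fraction = 1)
    expect_equal(cf$G[, "q0"], direct_autocorrelation(x, length(cf$lags)),
                 tolerance = 1e-10)
    expect_equal(cf$G[, "q2"], direct_autocorrelation(rev(x), length(cf$lags)),
                 tolerance = 1e-10)
  }
})

test_that("autocorrelate validates its inputs", {
  h <- structure(list(F0 = rep(1 + 0i, 50), F1 = rep(1 + 0i, 50),
                      F2 = rep(1 + 0i, 50), dt = 1),
                 class = "harmonic_series")
  expect_error(autocorrelate(h, truncation_fraction = 0), "truncation")
  expect_error(autocorrelate(h, truncation_fraction = 1.5), "truncation")
  short <- lapply(h[1:3], function(x) x[1:5])
  short$dt <- 1
  class(short) <- "harmonic_series"
  expect_error(autocorrelate(short), "short")
})

test_that("numeric spectral density reproduces the Lorentzian", {
  tau_c <- 20; dt <- 0.5; A <- 2
  lags <- seq(0, 400, by = dt)           # tau_max = 20 tau_c
  cf <- make_correlation_fn(lags, A * exp(-lags / tau_c), dt)
  # omega = 0: J = 2 A tau_c
  J0 <- spectral_density_numeric(cf, 0)
  expect_equal(J0$J1[1], 2 * A * tau_c, tolerance = 0.01)
  # omega tau_c = 1: half the zero-frequency value
  w1 <- 1 / (tau_c * 1e-12)              # rad/s
  J1 <- spectral_density_numeric(cf, w1)
  expect_equal(J1$J1[1], A * tau_c, tolerance = 0.01)
  # cosine symmetry: J(-w) = J(w) exactly
  expect_equal(spectral_density_numeric(cf, -w1)$J2,
               J1$J2, tolerance = 1e-15)
})

test_that("spectral density guards against unresolvable frequencies", {
  cf <- make_correlation_fn(seq(0, 50, 1), exp(-seq(0, 50, 1) / 5), 1)
  expect_error(spectral_density_numeric(cf, pi / 4 * 1e12 * 1.01), "pi/4")
  expect_error(spectral_density_numeric(normalize_correlation(cf), 0),
               "unnormalized")
})

test_that("correlation sums add magnitudes lag by lag", {
  lags <- seq(0, 30, 1)
  a <- make_correlation_fn(lags, exp(-lags / 5), 1)
  b <- make_correlation_fn(lags, 2 * exp(-lags / 10), 1)
  s <- sum_correlations(list(a, b))
  expect_equal(s$G[, "q1"], a$G[, "q1"] + b$G[, "q1"])
  expect_equal(unname(s$A["q0"]), 3)
})
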