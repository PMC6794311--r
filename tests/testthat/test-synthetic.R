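test_that("isotropic rotor is deterministic under the seed and rigid", {
  spec <- motion_spec("isotropic_rotor", dt = 0.5, n_steps = 200, seed = 7,
                      tau_c = 10, pair_distance = 0.2, n_pairs = 3)
  a <- generate_isotropic_rotor(spec)
  b <- generate_isotropic_rotor(spec)
  expect_identical(a$coords, b$coords)
  spec2 <- spec; spec2$seed <- 8L
  expect_false(identical(generate_isotropic_rotor(spec2)$coords, a$coords))
  # internuclear distance constant at pair_distance in every frame
  d <- a$coords[, 1, ] - a$coords[, 2, ]
  expect_equal(sqrt(rowSums(d^2)), rep(0.2, 200), tolerance = 1e-12)
})

test_that("single-frame rotor has no motion and exact geometry", {
  spec <- motion_spec("isotropic_rotor", dt = 1, n_steps = 1, seed = 1,
                      tau_c = 5, pair_distance = 0.158, n_pairs = 2)
  tr <- generate_isotropic_rotor(spec)
  expect_equal(n_frames(tr), 1L)
  d <- tr$coords[1, 1, ] - tr$coords[1, 2, ]
  expect_equal(sqrt(sum(d^2)), 0.158, tolerance = 1e-14)
})

test_that("too-coarse rotational steps are refused", {
  spec <- motion_spec("isotropic_rotor", dt = 10, n_steps = 100, seed = 1,
                      tau_c = 10, n_pairs = 1)
  expect_error(generate_isotropic_rotor(spec), "angular step variance")
})

test_that("rank-2 correlation of the rotor decays with the prescribed tau_c", {
  spec <- motion_spec("isotropic_rotor", dt = 0.1, n_steps = 4e4, seed = 7,
                      tau_c = 10, pair_distance = 0.158, n_pairs = 16)
  tr <- generate_isotropic_rotor(spec)
  lags <- seq(0, 300, by = 5)               # tau in [0, 30] ps
  m <- pair_p2_correlation(tr, lags)
  sel <- m > 0.1
  fit <- stats::lm(log(m[sel]) ~ I(lags[sel] * 0.1))
  expect_equal(-1 / coef(fit)[[2]], 10, tolerance = 0.05)
})

test_that("harmonic magnitudes match the uniform-sphere moments", {
  # A_0 : A_1 : A_2 -> (4/5, 2/15, 8/15) r^-6, i.e. 12 : 2 : 8
  spec <- motion_spec("isotropic_rotor", dt = 0.5, n_steps = 1e4, seed = 3,
                      tau_c = 5, pair_distance = 0.158, n_pairs = 16)
  tr <- generate_isotropic_rotor(spec)
  A <- t(vapply(seq(1, 32, by = 2), function(i) {
    cf <- autocorrelate(harmonics_from_polar(pair_polar_series(tr, i, i + 1)))
    cf$A * 0.158^6
  }, numeric(3)))
  theo <- c(4 / 5, 2 / 15, 8 / 15)
  for (q in 1:3) {
    se <- stats::sd(A[, q]) / sqrt(nrow(A))
    expect_lt(abs(mean(A[, q]) - theo[q]), 3 * se)
  }
})

test_that("cone rotor validates its spec and records ground truth", {
  expect_error(motion_spec("cone_restricted_rotor", dt = 1, n_steps = 10,
                           S2_target = 1.2, tau_M = 100, tau_i = 5),
               "S2_target")
  expect_error(motion_spec("cone_restricted_rotor", dt = 1, n_steps = 10,
                           S2_target = 0, tau_M = 100, tau_i = 5),
               "isotropic_rotor")
  expect_error(motion_spec("cone_restricted_rotor", dt = 1, n_steps = 10,
                           S2_target = 0.5, tau_M = 100, tau_i = 200),
               "tau_i < tau_M")
  spec <- motion_spec("cone_restricted_rotor", dt = 1, n_steps = 50,
                      seed = 2, S2_target = 0.64, tau_M = 500, tau_i = 20,
                      n_pairs = 2)
  tr <- generate_cone_restricted_rotor(spec)
  expect_equal(tr$metadata$S2, 0.64)
  expect_equal(tr$metadata$tau_M, 500)
})

test_that("cone order-parameter mapping inverts the closed form", {
  for (S2 in c(0.1, 0.36, 0.64, 0.81, 0.95)) {
    b <- cone_half_angle(S2)
    expect_equal((cos(b) * (1 + cos(b)) / 2)^2, S2, tolerance = 1e-9)
  }
  expect_equal(cone_half_angle(1), 0)
})

test_that("S2 = 1 cone rotor degenerates to a single-exponential global rotor", {
  spec <- motion_spec("cone_restricted_rotor", dt = 1, n_steps = 3e4,
                      seed = 5, S2_target = 1, tau_M = 100, tau_i = 10,
                      n_pairs = 8)
  tr <- generate_cone_restricted_rotor(spec)
  lags <- seq(0, 300, by = 5)
  m <- pair_p2_correlation(tr, lags)
  expect_equal(m[1], 1, tolerance = 1e-12)   # normalized at lag 0
  sel <- m > 0.1
  fit <- stats::lm(log(m[sel]) ~ lags[sel])
  expect_equal(-1 / coef(fit)[[2]], 100, tolerance = 0.10)
})

test_that("translational generator obeys its degenerate limits", {
  spec0 <- motion_spec("translational_brownian", dt = 1, n_steps = 50,
                       seed = 1, D = 0, n_molecules = 4)
  tr0 <- generate_translational_brownian(spec0)
  expect_true(all(tr0$coords == tr0$coords[rep(1, 50), , ]))
  spec <- motion_spec("translational_brownian", dt = 0.5, n_steps = 500,
                      seed = 2, D = 2e-5, n_molecules = 10)
  msd <- estimate_diffusion(generate_translational_brownian(spec))$msd
  expect_equal(msd$msd_nm2[1], 0)
  expect_true(all(msd$msd_nm2 >= 0))
})

test_that("water slab respects reflecting walls and validates its profile", {
  W <- 2
  prof <- list(tau_c = function(z) rep(5, length(z)),
               D = function(z) rep(2e-5, length(z)))
  spec <- motion_spec("water_slab", dt = 0.5, n_steps = 2000, seed = 4,
                      slab_width = W, mobility_profile = prof,
                      n_molecules = 10)
  tr <- generate_water_slab(spec)
  z <- tr$coords[, , 3]
  # pair midpoints stay inside; atoms can stick out by at most half the
  # H-H distance
  mids <- (z[, seq(1, 20, 2)] + z[, seq(2, 20, 2)]) / 2
  expect_true(all(mids >= 0 & mids <= W))
  bad <- list(tau_c = function(z) 5 - z * 10, D = function(z) rep(2e-5, length(z)))
  expect_error(generate_water_slab(
    motion_spec("water_slab", dt = 0.5, n_steps = 10, seed = 1,
                slab_width = W, mobility_profile = bad, n_molecules = 2)),
    "positive")
})
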