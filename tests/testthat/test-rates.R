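# analytic Lorentzian spectral densities of a rigid isotropic pair, in
# nm^-6 ps: J_q(w) = 2 A_q tau_c / (1 + w^2 tau_c^2)
lorentz_J <- function(q, omega, r, tau_c) {
  A <- c(4 / 5, 2 / 15, 8 / 15)[q + 1] / r^6
  J <- 2 * A * tau_c / (1 + (omega * 1e-12 * tau_c)^2)
  attr(J, "units") <- NULL
  J
}

test_that("rate assembly matches the closed-form two-spin rate", {
  r <- 0.158; tau_c <- 2.5
  for (B0 in c(1.5, 3, 7)) {
    f <- field_spec(B0)
    J1 <- as_si_J(lorentz_J(1, f$omega_L, r, tau_c))
    J2 <- as_si_J(lorentz_J(2, 2 * f$omega_L, r, tau_c))
    expect_equal(r1_pair_sum(J1, J2, f), bpp_r1(r, tau_c, B0),
                 tolerance = 1e-12)
  }
  # extreme narrowing anchor: ~0.138 Hz at 1.5 T
  f <- field_spec(1.5)
  expect_equal(r1_pair_sum(as_si_J(lorentz_J(1, f$omega_L, r, tau_c)),
                           as_si_J(lorentz_J(2, 2 * f$omega_L, r, tau_c)),
                           f),
               0.138, tolerance = 0.01)
})

test_that("rate assembly refuses non-SI spectral densities and is linear", {
  f <- field_spec(3)
  expect_error(r1_pair_sum(1e-3, 1e-3, f), "SI")
  J <- as_si_J(c(1e-3, 2e-3))
  expect_equal(r1_pair_sum(J, J, f) * 2,
               r1_pair_sum(as_si_J(2 * c(1e-3, 2e-3)),
                           as_si_J(2 * c(1e-3, 2e-3)), f))
  expect_equal(r1_pair_sum(as_si_J(0), as_si_J(0), f), 0)
})

test_that("auto and cross rates obey the flat-J and sign limits", {
  f <- field_spec(3)
  J <- as_si_J(1e-3)
  ac <- auto_cross_pair_sum(J, J, J, f)
  expect_equal(ac$cross / ac$auto, 2 / 7, tolerance = 1e-14)
  # slow motion: J0 dominates -> negative cross rate
  slow <- auto_cross_pair_sum(as_si_J(1e-2), as_si_J(1e-5),
                              as_si_J(1e-6), f)
  expect_lt(slow$cross, 0)
  # exact cancellation at J0 = 9 J2
  zero <- auto_cross_pair_sum(as_si_J(9e-3), as_si_J(5e-4),
                              as_si_J(1e-3), f)
  expect_equal(zero$cross, 0)
})

test_that("pool averages reduce correctly and reject empty pools", {
  df <- data.frame(proton = 1:4, pool = "WP", B0_T = 3,
                   R1_Hz = rep(2.5, 4))
  avg <- pool_average(df)
  expect_equal(avg$R1_Hz_mean, 2.5)
  expect_equal(avg$R1_Hz_se, 0)
  expect_equal(avg$n, 4)
  expect_error(pool_average(df[0, ]), "empty")
  expect_error(subsample_protons(
    spin_trajectory(array(0, c(1, 2, 3)), 1), "MP"), "empty")
})

test_that("detailed balance holds to machine precision on shared J sets", {
  tr <- make_two_pool_rotors(n_wp = 2, n_mp = 3, n_steps = 2000)
  rates <- cross_pool_rates(tr, fields_T = 3)
  wp <- rates[rates$pool == "WP", ]
  mp <- rates[rates$pool == "MP", ]
  lhs <- nrow(wp) * mean(wp$cross_Hz)
  rhs <- nrow(mp) * mean(mp$cross_Hz)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  lhs_a <- nrow(wp) * mean(wp$auto_Hz)
  rhs_a <- nrow(mp) * mean(mp$auto_Hz)
  expect_equal(lhs_a, rhs_a, tolerance = 1e-12)
})

test_that("effective rates add the auto contribution", {
  tab <- reference_rate_table()
  eff <- effective_rates(tab)
  expect_equal(eff$effective_Hz[eff$pool == "WP" & eff$B0_T == 1.5],
               1.34)
  expect_equal(eff$effective_Hz[eff$pool == "WP" & eff$B0_T == 7],
               0.813)
  tab0 <- tab; tab0$auto_Hz <- 0
  expect_equal(effective_rates(tab0)$effective_Hz, tab0$intra_Hz)
})

test_that("power-law fits recover exact inputs and interpolate two points", {
  B0 <- c(1.5, 3, 7)
  fit <- fit_power_law(B0, 2 * B0^-0.5)
  expect_equal(fit$n0, 2, tolerance = 1e-9)
  expect_equal(fit$n1, -0.5, tolerance = 1e-9)
  two <- fit_power_law(c(2, 5), c(1.8, 1.1))
  expect_equal(predict(two, c(2, 5)), c(1.8, 1.1), tolerance = 1e-9)
  expect_lt(two$residual, 1e-18)
  expect_error(fit_power_law(c(1, 2), c(1, -1)), "positive")
  expect_error(fit_power_law(c(2, 2), c(1, 1)), "distinct")
})

test_that("sheath averages interpolate between the pool rates", {
  fw <- fit_power_law(c(1.5, 3, 7), 1.5 * c(1.5, 3, 7)^-0.3)
  fm <- fit_power_law(c(1.5, 3, 7), 6 * c(1.5, 3, 7)^-0.45)
  s <- sheath_average(fw, fm, n_wp = 0, n_mp = 100, B0 = 3)
  expect_equal(s$R1_MS, predict(fm, 3))
  s2 <- sheath_average(fw, fw, n_wp = 50, n_mp = 50, B0 = 3)
  expect_equal(s2$R1_MS, predict(fw, 3))
  s3 <- sheath_average(fw, fm, 9398, 13810, 7)
  expect_true(s3$R1_MS >= min(s3$R1_WP_ef, s3$R1_MP_ef) &&
                s3$R1_MS <= max(s3$R1_WP_ef, s3$R1_MP_ef))
})

test_that("exchange totals pass through and flag negative cross rates", {
  ex <- exchange_total(0.061, 11.94)
  expect_equal(ex$k_WP, 12.001)
  expect_equal(ex$cross_fraction, 0.061 / 12.001)
  expect_equal(exchange_total(0.05, 0)$k_WP, 0.05)
  expect_true(exchange_total(-0.01, 1)$negative_cross)
})

test_that("windowed profiles validate the window length", {
  spec <- motion_spec("isotropic_rotor", dt = 1, n_steps = 100, seed = 1,
                      tau_c = 10, n_pairs = 2)
  tr <- generate_isotropic_rotor(spec)
  expect_error(windowed_profile(tr, window_ps = 500, n_windows = 5,
                                field = field_spec(3)), "longer than")
})

test_that("pool-averaged R1 does not increase with field strength", {
  spec <- motion_spec("isotropic_rotor", dt = 2, n_steps = 3e4, seed = 21,
                      tau_c = 200, n_pairs = 8)
  tr <- generate_isotropic_rotor(spec)
  r <- pool_r1(tr, protons = seq(1, 16, 2), fields_T = c(1.5, 3, 7),
               truncation_fraction = 0.02, cutoff = 2)
  avg <- pool_average(r)
  avg <- avg[order(avg$B0_T), ]
  expect_true(all(diff(avg$R1_Hz_mean) <= 0))
})
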