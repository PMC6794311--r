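# independent oracles and small fixture builders used across the suite

# brute-force O(N^2) lag autocorrelation of a complex series:
# Re < x(t) x*(t+k) > with unbiased divisor
direct_autocorrelation <- function(x, n_lag) {
  vapply(0:(n_lag - 1L), function(k) {
    t <- seq_len(length(x) - k)
    mean(Re(x[t] * Conj(x[t + k])))
  }, 0)
}

# second Legendre polynomial
P2 <- function(x) (3 * x^2 - 1) / 2

# rank-2 orientational correlation of pair unit vectors, averaged over the
# pair molecules of a trajectory
pair_p2_correlation <- function(traj, lags) {
  mols <- unique(traj$molecule_id)
  cors <- vapply(mols, function(m) {
    ij <- which(traj$molecule_id == m)
    u <- traj$coords[, ij[1], ] - traj$coords[, ij[2], ]
    u <- u / sqrt(rowSums(u^2))
    vapply(lags, function(k) {
      t <- seq_len(nrow(u) - k)
      mean(P2(rowSums(u[t, , drop = FALSE] * u[t + k, , drop = FALSE])))
    }, 0)
  }, numeric(length(lags)))
  rowMeans(cors)
}

# correlation_fn object built directly from a closed-form curve
make_correlation_fn <- function(lags, G, dt, normalized = FALSE) {
  G <- cbind(q0 = G, q1 = G, q2 = G)
  structure(list(lags = lags, G = G, A = G[1, ], dt = dt,
                 normalized = normalized, truncation_fraction = 1),
            class = "correlation_fn")
}

# tiny two-pool trajectory: n_wp + n_mp isotropically tumbling pairs with
# pools split across molecules (used for detailed-balance checks)
make_two_pool_rotors <- function(n_wp = 2, n_mp = 3, n_steps = 2000,
                                 dt = 0.5, tau_c = 10, seed = 42) {
  spec <- motion_spec("isotropic_rotor", dt = dt, n_steps = n_steps,
                      seed = seed, tau_c = tau_c, n_pairs = n_wp + n_mp)
  tr <- generate_isotropic_rotor(spec)
  pool <- rep(c("WP", "MP"), c(2 * n_wp, 2 * n_mp))
  tr$pool <- pool
  tr$species <- ifelse(pool == "WP", "SOL", "MAC")
  tr
}
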