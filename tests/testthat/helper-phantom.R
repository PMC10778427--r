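# Shared fixtures: small phantoms and analytic forward-model oracles.

tiny_spec <- function(sigma = 0, seed = 1L, grid = 24L,
                      model = "gaussian", regions = default_region_params()) {
  phantom_spec(grid_shape = rep(grid, 3), voxel_size = c(2, 2, 2),
               region_params = regions,
               noise = list(model = model, sigma = sigma), seed = seed)
}

tiny_truth <- function(...) build_phantom(tiny_spec(...))

# Direct evaluation of the piecewise log-signal decay, written
# independently of the package's vectorized implementation.
oracle_ln_signal <- function(tau_ms, S0, R2, TE_ms, R2prime, DBV,
                             tau_c_ms = 16) {
  tau <- tau_ms / 1000
  base <- log(S0) - R2 * TE_ms / 1000
  if (tau_ms < tau_c_ms) {
    base - 0.3 * (R2prime * tau)^2 / DBV
  } else {
    base + DBV - R2prime * tau
  }
}

# Direct arithmetic for the OEF relation with the printed constants.
oracle_oef <- function(R2prime, DBV, gamma = 267.5e6, B0 = 3,
                       dchi0 = 0.264e-6, Hct = 0.4) {
  (3 * R2prime) / (4 * pi * gamma * B0 * dchi0 * Hct * DBV)
}

# Single-voxel ASE series straight from parameters (bypasses the phantom).
voxel_ase <- function(R2prime, DBV, S0 = 100, R2 = 12,
                      taus_ms = c(0, seq(16, 60, by = 4)), TE_ms = 74,
                      n_rep = 1L) {
  lnS <- vapply(taus_ms, oracle_ln_signal, numeric(1),
                S0 = S0, R2 = R2, TE_ms = TE_ms,
                R2prime = R2prime, DBV = DBV)
  data <- array(rep(exp(lnS), each = n_rep),
                c(n_rep, 1, 1, length(taus_ms)))
  ase_series(data, taus_ms = taus_ms, TE_ms = TE_ms)
}
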