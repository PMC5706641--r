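# shared fixtures and independent numerical oracles

# resting-state truth used across tests
resting_network <- function() {
  exchange_network(k1 = 0.37, k2 = 0.19, T1_PCr = 5.1, T1_Pi = 3.0)
}

# the simulation-study truth of the Monte Carlo analyses
mc_network <- function() {
  exchange_network(k1 = 0.3, k2 = 0.2, T1_PCr = 5, T1_Pi = 3)
}

# independent fixed-step RK4 integrator for the clamped single-pool ODE
#   dM/dt = (M0 - M)/T1 - k M        (partner clamped at zero)
# kept deliberately separate from the package's eigen-based solver
rk4_clamped <- function(k, T1, t_end, M0 = 1, M_init = M0, dt = 1e-3) {
  f <- function(M) (M0 - M) / T1 - k * M
  M <- M_init
  n <- ceiling(t_end / dt)
  h <- t_end / max(n, 1)
  for (i in seq_len(n)) {
    k1 <- f(M); k2 <- f(M + h * k1 / 2)
    k3 <- f(M + h * k2 / 2); k4 <- f(M + h * k3)
    M <- M + h * (k1 + 2 * k2 + 2 * k3 + k4) / 6
  }
  M
}

# published 7-point saturation-time grid (s)
paper_tsat_grid <- function() c(0, 0.565, 1.058, 2.045, 3.032, 5.005, 8.295)
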