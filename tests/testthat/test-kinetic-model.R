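# three-pool exchange model: closed forms, ODE solver, estimators

test_that("exchange network derives reverse rates from flux balance", {
  net <- exchange_network(k1 = 0.35, k2 = 0.15, M0_PCr = 1.22, M0_Pi = 0.54)
  expect_equal(net$k_reverse[["k_1"]] * net$M0[["ATP"]],
               net$k_forward[["k1"]] * net$M0[["PCr"]])
  expect_equal(net$k_reverse[["k_2"]] * net$M0[["ATP"]],
               net$k_forward[["k2"]] * net$M0[["Pi"]])
  expect_error(exchange_network(T1_PCr = -1), "T1")
  expect_error(exchange_network(k1 = -0.1), "rate constants")
  expect_error(exchange_network(M0_Pi = 0), "magnetizations")
})

test_that("progressive closed form matches its definition and the RK4 oracle", {
  # frozen values computed from (k/R) exp(-R t) + 1/(R T1int)
  expect_equal(progressive_signal(0.3, 5, 0), 1.0)
  expect_equal(progressive_signal(0.3, 5, 2), 0.6207277, tolerance = 1e-6)
  expect_equal(progressive_signal(0.2, 3, 3), 0.7007112, tolerance = 1e-6)
  # independent check: numerical integration of the clamped ODE
  expect_equal(progressive_signal(0.3, 5, 2), rk4_clamped(0.3, 5, 2),
               tolerance = 1e-8)
  expect_equal(progressive_signal(0.2, 3, 3), rk4_clamped(0.2, 3, 3),
               tolerance = 1e-8)
  expect_error(progressive_signal(-0.1, 5, 1), "require")
  expect_error(progressive_signal(0.3, 5, -1), "require")
})

test_that("clamped evolution agrees with the closed form to 1e-6 over a grid", {
  for (k in c(0, 0.1, 0.3, 0.6, 1.2)) {
    for (T1 in c(0.5, 1, 3, 5, 10)) {
      net <- exchange_network(k1 = k, k2 = k / 2 + 0.01, T1_PCr = T1,
                              T1_Pi = max(T1 / 2, 0.3))
      tr <- evolve_network(net, atp_clamped = TRUE, duration = 20,
                           n_steps = 41)
      frac <- tr$M_PCr / net$M0[["PCr"]]
      expect_equal(frac, progressive_signal(k, T1, tr$time_s),
                   tolerance = 1e-6)
    }
  }
})

test_that("evolution without exchange decouples the pools", {
  net <- exchange_network(k1 = 0, k2 = 0, T1_PCr = 5, T1_Pi = 3, T1_ATP = 1)
  tr <- evolve_network(net, atp_clamped = TRUE,
                       initial_M = c(PCr = 0.2, ATP = 0, Pi = 2),
                       duration = 6, n_steps = 13)
  # each pool relaxes mono-exponentially to M0 with its own T1int
  expect_equal(tr$M_PCr,
               net$M0[["PCr"]] + (0.2 - net$M0[["PCr"]]) * exp(-tr$time_s / 5),
               tolerance = 1e-9)
  expect_equal(tr$M_Pi,
               net$M0[["Pi"]] + (2 - net$M0[["Pi"]]) * exp(-tr$time_s / 3),
               tolerance = 1e-9)
})

test_that("clamped fixed point and unclamped equilibrium are correct", {
  net <- mc_network()
  tr <- evolve_network(net, atp_clamped = TRUE, duration = 200, n_steps = 2)
  expect_equal(tr$M_PCr[2] / net$M0[["PCr"]], 1 / (1 + 0.3 * 5),
               tolerance = 1e-9)
  expect_equal(tr$M_Pi[2] / net$M0[["Pi"]], 1 / (1 + 0.2 * 3),
               tolerance = 1e-9)
  # free evolution from equilibrium stays at equilibrium
  tr2 <- evolve_network(net, atp_clamped = FALSE, duration = 10, n_steps = 5)
  expect_equal(tr2$M_PCr, rep(net$M0[["PCr"]], 5), tolerance = 1e-10)
  expect_equal(tr2$M_ATP, rep(net$M0[["ATP"]], 5), tolerance = 1e-10)
  # and from zero it recovers towards equilibrium
  tr3 <- evolve_network(net, atp_clamped = FALSE,
                        initial_M = c(PCr = 0, ATP = 0, Pi = 0),
                        duration = 60, n_steps = 3)
  expect_equal(tr3$M_Pi[3], net$M0[["Pi"]], tolerance = 1e-6)
})

test_that("steady-state rate estimator inverts the saturation fixed point", {
  expect_equal(as.numeric(steady_state_rate(100, 40, 5)), 0.3)
  expect_equal(as.numeric(steady_state_rate(7, 7, 3)), 0)
  # round trip with the clamped fixed point
  minf <- 1 / (1 + 0.35 * 5.1)
  expect_equal(as.numeric(steady_state_rate(1, minf, 5.1)), 0.35,
               tolerance = 1e-12)
  # general inversion property across a grid
  for (k in c(0.05, 0.19, 0.37, 1)) {
    for (T1 in c(1, 3, 5.1)) {
      expect_equal(
        as.numeric(steady_state_rate(1, progressive_signal(k, T1, Inf), T1)),
        k, tolerance = 1e-12)
    }
  }
  # noise pushing Minf above M0 gives a flagged negative estimate
  k <- steady_state_rate(1, 1.04, 5)
  expect_lt(as.numeric(k), 0)
  expect_true(attr(k, "negative"))
  expect_error(steady_state_rate(1, 0, 5), "Minf")
})

test_that("rate from the steady-state formula scales exactly as 1/T1int", {
  k0 <- as.numeric(steady_state_rate(1, 0.4, 5))
  expect_equal(as.numeric(steady_state_rate(1, 0.4, 5 * 1.2)), k0 / 1.2)
  expect_equal(as.numeric(steady_state_rate(1, 0.4, 5 * 1.4)), k0 / 1.4)
})

test_that("apparent relaxation matches the printed apparent T1 values", {
  expect_equal(apparent_relaxation(0, 5)[["T1app"]], 5)
  # Pi: k2 = 0.19, T1int = 3.0 -> 1.91 s (printed 1.9 +/- 0.7)
  expect_equal(apparent_relaxation(0.19, 3.0)[["T1app"]], 1.9108, tolerance = 1e-4)
  expect_equal(apparent_relaxation(0.19, 3.0)[["T1app"]], 1.9, tolerance = 0.01)
  # PCr: k1 = 0.37, T1int = 5.1 -> 1.77 s (printed 1.7, from unrounded fits)
  expect_equal(apparent_relaxation(0.37, 5.1)[["T1app"]], 1.7665, tolerance = 1e-4)
  # T1app < T1int whenever k > 0
  expect_lt(apparent_relaxation(0.01, 5)[["T1app"]], 5)
})

test_that("concentrations, fluxes and unit conversions reproduce the worked values", {
  expect_equal(concentration_from_ratio(1.22, 3), 3.66)
  expect_equal(concentration_from_ratio(0.540, 3), 1.62)
  expect_equal(concentration_from_ratio(0, 3), 0)
  f <- forward_flux(0.15, 1.6, 1.1)
  expect_equal(f[["flux_mM_s"]], 0.24)
  expect_equal(f[["flux_umol_g_min"]], 13.0909, tolerance = 1e-4)
  expect_equal(flux_to_umol_g_min(1.32, 1.1), 72.0)
  expect_equal(unname(forward_flux(0, 2)), c(0, 0))
  # unit round trip is an identity
  for (x in c(0.1, 1.32, 2.4))
    expect_equal(flux_to_mM_s(flux_to_umol_g_min(x)), x)
})

test_that("pH calibration behaves as a monotone Henderson-Hasselbalch curve", {
  cal <- ph_calibration()
  mid <- (cal$delta_acid_ppm + cal$delta_base_ppm) / 2
  expect_equal(ph_from_shift(mid), cal$pKa)
  expect_equal(ph_from_shift(4.795), 7.0006, tolerance = 1e-4)
  d <- seq(3.4, 5.5, by = 0.1)
  expect_true(all(diff(ph_from_shift(d)) > 0))
  # inverse round trip
  for (pH in c(6.8, 6.99, 7.2))
    expect_equal(ph_from_shift(shift_from_ph(pH)), pH, tolerance = 1e-10)
  expect_error(ph_from_shift(3.0), "calibration range")
  expect_error(ph_from_shift(6.0), "calibration range")
})

test_that("oxidative phosphorylation cross-check multiplies CMRO2 by P:O2", {
  expect_equal(oxphos_flux_from_cmro2(1.71, 6), 10.26)
  expect_equal(oxphos_flux_from_cmro2(0.5, 6), 3.0)
  expect_equal(oxphos_flux_from_cmro2(2.2, 1), 2.2)
})

test_that("progressive fit recovers noiseless truth exactly on the published grid", {
  net <- resting_network()
  ser <- generate_mt_series(net, noise_sd = 0)
  for (spec in list(c(pool = "PCr", k = 0.37, T1 = 5.1),
                    c(pool = "Pi", k = 0.19, T1 = 3.0))) {
    fit <- fit_progressive(ser, spec[["pool"]])
    expect_equal(fit$k, as.numeric(spec[["k"]]), tolerance = 1e-6)
    expect_equal(fit$T1int, as.numeric(spec[["T1"]]), tolerance = 1e-6)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
    expect_true(fit$t1_identifiable)
    expect_lt(fit$T1app, fit$T1int)
  }
})

test_that("progressive fit flags unidentifiable and degenerate inputs", {
  flat <- data.frame(t_sat_s = paper_tsat_grid(),
                     area_PCr = 1, area_Pi = 1, area_gATP = 1)
  fit <- suppressWarnings(fit_progressive(flat, "PCr"))
  expect_false(fit$t1_identifiable)
  expect_lt(fit$k, 1e-6)
  two <- data.frame(t_sat_s = c(0, 5), area_PCr = c(1, 0.5),
                    area_Pi = c(1, 0.7), area_gATP = c(1, 0.05))
  expect_error(fit_progressive(two, "PCr"), "3 distinct")
  noref <- data.frame(t_sat_s = c(1, 2, 5), area_PCr = c(1, .8, .6),
                      area_Pi = 1, area_gATP = 1)
  expect_error(fit_progressive(noref, "PCr"), "reference")
})
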