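#' Configuration of the Monte Carlo error studies
#'
#' The two simulation studies share a configuration: the true kinetic
#' parameters, the saturation-time design, the measurement noise and the
#' replicate count.  Defaults follow the published simulation setup
#' (`T1int` 5 s / 3 s, `k1` 0.3 1/s, `k2` 0.2 1/s, 1000 replicates, the
#' 7-point progressive grid or the \{0, 10 s\} steady-state pair) with the
#' calibrated noise level: 1.5% of the PCr Boltzmann area per spectrum,
#' with Pi carrying the same absolute noise (both signals live in the same
#' spectrum), hence a larger relative noise on the smaller Pi peak.
#'
#' @param k1,k2 true forward rate constants (1/s).
#' @param T1_PCr,T1_Pi true intrinsic relaxation times (s).
#' @param t_sat_progressive progressive design (s).
#' @param t_sat_steady two-point steady-state design (s).
#' @param amp_PCr,amp_Pi Boltzmann areas (gamma-ATP units) fixing the
#'   relative noise of the two signals.
#' @param noise_frac noise sd as a fraction of the PCr Boltzmann area.
#' @param n_replicates number of Monte Carlo replicates (`>= 2`).
#' @param t1_error_levels relative errors in the assumed `T1int` for the
#'   rate-sensitivity study.
#' @param seed integer seed.
#' @return a list of class `mc_config`.
#' @export
mc_config <- function(k1 = 0.3, k2 = 0.2, T1_PCr = 5, T1_Pi = 3,
                      t_sat_progressive =
                        c(0, 0.565, 1.058, 2.045, 3.032, 5.005, 8.295),
                      t_sat_steady = c(0, 10),
                      amp_PCr = 1.22, amp_Pi = 0.540,
                      noise_frac = 0.015,
                      n_replicates = 1000,
                      t1_error_levels = c(0, 0.2, 0.4),
                      seed = 1L) {
  if (n_replicates < 2) stop("n_replicates must be >= 2", call. = FALSE)
  if (noise_frac < 0) stop("noise_frac must be >= 0", call. = FALSE)
  structure(list(k1 = k1, k2 = k2, T1_PCr = T1_PCr, T1_Pi = T1_Pi,
                 t_sat_progressive = t_sat_progressive,
                 t_sat_steady = t_sat_steady,
                 amp_PCr = amp_PCr, amp_Pi = amp_Pi,
                 noise_frac = noise_frac,
                 noise_sd = noise_frac * amp_PCr,
                 n_replicates = as.integer(n_replicates),
                 t1_error_levels = t1_error_levels,
                 seed = as.integer(seed)),
            class = "mc_config")
}

#' Monte Carlo uncertainty of the intrinsic T1 estimates
#'
#' Simulates `n_replicates` noisy progressive-saturation experiments from
#' the true model, fits each with [fit_progressive()] (identical bounds and
#' multi-start as the production fitter, so no method variance is added)
#' and summarizes the distribution of the fitted `T1int` of PCr and Pi.
#' Non-convergent replicates are counted and excluded from the moments.
#'
#' @param config an [mc_config()] with the progressive design.
#' @return an `mc_result`: list with `table` (parameter, true value, mean,
#'   sd, CV%), per-parameter estimate vectors in `estimates`, and
#'   `n_failed`.
#' @export
mc_t1_recovery <- function(config = mc_config()) {
  stopifnot(inherits(config, "mc_config"))
  set.seed(config$seed)
  ts <- config$t_sat_progressive
  if (length(unique(ts)) < 4)
    stop("progressive design needs the multi-point t_sat grid", call. = FALSE)
  nrep <- config$n_replicates
  truth <- list(PCr = c(k = config$k1, T1int = config$T1_PCr),
                Pi = c(k = config$k2, T1int = config$T1_Pi))
  amps <- c(PCr = config$amp_PCr, Pi = config$amp_Pi)
  curves <- list(
    PCr = amps[["PCr"]] * progressive_signal(config$k1, config$T1_PCr, ts),
    Pi = amps[["Pi"]] * progressive_signal(config$k2, config$T1_Pi, ts))

  est <- list(PCr = matrix(NA_real_, nrep, 2, dimnames = list(NULL, c("k", "T1int"))),
              Pi = matrix(NA_real_, nrep, 2, dimnames = list(NULL, c("k", "T1int"))))
  n_failed <- c(PCr = 0L, Pi = 0L)
  for (r in seq_len(nrep)) {
    noisy <- data.frame(
      t_sat_s = ts,
      area_PCr = curves$PCr + stats::rnorm(length(ts), 0, config$noise_sd),
      area_Pi = curves$Pi + stats::rnorm(length(ts), 0, config$noise_sd),
      area_gATP = 1)
    for (p in c("PCr", "Pi")) {
      fit <- tryCatch(suppressWarnings(fit_progressive(noisy, p)),
                      error = function(e) NULL)
      if (is.null(fit)) n_failed[p] <- n_failed[p] + 1L
      else est[[p]][r, ] <- c(fit$k, fit$T1int)
    }
  }

  rows <- lapply(c("PCr", "Pi"), function(p) {
    x <- est[[p]][, "T1int"]
    x <- x[is.finite(x)]
    data.frame(parameter = paste0("T1int_", p),
               true_value = truth[[p]][["T1int"]],
               mean = mean(x), sd = stats::sd(x),
               cv_pct = 100 * stats::sd(x) / mean(x))
  })
  out <- list(table = do.call(rbind, rows), estimates = est,
              n_failed = n_failed, config = config)
  class(out) <- "mc_result"
  out
}

#' Monte Carlo sensitivity of the steady-state rate constants to T1 error
#'
#' Simulates noisy two-point (Boltzmann, steady-state) measurements and
#' computes `k1`/`k2` via [steady_state_rate()] under different relative
#' errors in the assumed intrinsic T1.  Because the estimator scales as
#' `1/T1int`, a T1 error biases the mean multiplicatively by `1/(1+error)`
#' but leaves the coefficient of variation essentially unchanged; the CV is
#' the quantity of interest.
#'
#' @param config an [mc_config()] with the two-point design.
#' @return an `mc_result`: `table` has one row per T1-error level with
#'   mean, sd and CV% of `k1` and `k2`.
#' @export
mc_rate_sensitivity <- function(config = mc_config()) {
  stopifnot(inherits(config, "mc_config"))
  set.seed(config$seed)
  ts <- config$t_sat_steady
  if (length(ts) != 2 || ts[1] != 0)
    stop("steady-state design must be the {0, t_long} pair", call. = FALSE)
  nrep <- config$n_replicates
  t_long <- ts[2]
  amps <- c(PCr = config$amp_PCr, Pi = config$amp_Pi)
  minf <- c(PCr = amps[["PCr"]] *
              progressive_signal(config$k1, config$T1_PCr, t_long),
            Pi = amps[["Pi"]] *
              progressive_signal(config$k2, config$T1_Pi, t_long))
  T1 <- c(PCr = config$T1_PCr, Pi = config$T1_Pi)
  ktrue <- c(PCr = config$k1, Pi = config$k2)

  rows <- lapply(config$t1_error_levels, function(lev) {
    stats_k <- lapply(c("PCr", "Pi"), function(p) {
      M0 <- amps[[p]] + stats::rnorm(nrep, 0, config$noise_sd)
      Mi <- minf[[p]] + stats::rnorm(nrep, 0, config$noise_sd)
      ok <- Mi > 0 & M0 > 0
      k <- (M0[ok] - Mi[ok]) / (Mi[ok] * (T1[[p]] * (1 + lev)))
      c(mean = mean(k), sd = stats::sd(k),
        cv = 100 * stats::sd(k) / mean(k), nfail = sum(!ok))
    })
    data.frame(t1_error = lev,
               mean_k1 = stats_k[[1]][["mean"]], sd_k1 = stats_k[[1]][["sd"]],
               cv_k1_pct = stats_k[[1]][["cv"]],
               mean_k2 = stats_k[[2]][["mean"]], sd_k2 = stats_k[[2]][["sd"]],
               cv_k2_pct = stats_k[[2]][["cv"]],
               true_k1 = ktrue[["PCr"]] / (1 + lev),
               true_k2 = ktrue[["Pi"]] / (1 + lev),
               n_failed = stats_k[[1]][["nfail"]] + stats_k[[2]][["nfail"]])
  })
  out <- list(table = do.call(rbind, rows), config = config)
  class(out) <- "mc_result"
  out
}

#' @export
print.mc_result <- function(x, ...) {
  cat("Monte Carlo error analysis (", x$config$n_replicates,
      " replicates)\n", sep = "")
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Partial-saturation bias of the measured saturation-transfer ratio
#'
#' With a finite TR the magnetization never fully recovers between
#' excitations, so both the Boltzmann reference and the saturated
#' measurement are attenuated and their ratio deviates from the fully
#' relaxed ideal.  The acquisition cycle (saturate/recover for `t_sat`
#' with ATP clamped, excite to zero, free recovery for `TR - t_sat`) is
#' simulated to its cyclic steady state with [evolve_network()], the
#' reference cycle likewise with no saturation, and the fractional
#' deviation of the measured `M(t_sat)/M0` ratio from
#' [progressive_signal()] is returned per pool.
#'
#' @param network an [exchange_network()].
#' @param acq an [acq_params()] supplying the TR.
#' @param t_sat saturation time (s); must be below the TR.
#' @param n_cycles maximum number of repetitions simulated (at least 5).
#' @param tol convergence tolerance on the cycle fixed point.
#' @return named numeric vector of signed fractional deviations for `PCr`
#'   and `Pi` (positive: the ratio is overestimated, so the rate constant
#'   would be underestimated), with attribute `converged`.
#' @export
partial_saturation_bias <- function(network, acq = acq_params(), t_sat = 10,
                                    n_cycles = 20, tol = 1e-10) {
  stopifnot(inherits(network, "exchange_network"))
  TR <- acq$TR_s
  if (t_sat >= TR) stop("require t_sat < TR", call. = FALSE)
  n_cycles <- max(5L, n_cycles)

  last_row <- function(tr) as.numeric(tr[nrow(tr), c("M_PCr", "M_ATP", "M_Pi")])
  run_cycle <- function(M, sat_time) {
    if (sat_time > 0) {
      tr <- evolve_network(network, atp_clamped = TRUE,
                           initial_M = stats::setNames(M, c("PCr", "ATP", "Pi")),
                           duration = sat_time, n_steps = 2)
      M <- last_row(tr)
    }
    measured <- M
    # excitation reads out and destroys longitudinal magnetization
    rec <- evolve_network(network, atp_clamped = FALSE,
                          initial_M = c(PCr = 0, ATP = 0, Pi = 0),
                          duration = TR - sat_time, n_steps = 2)
    list(measured = measured, M = last_row(rec))
  }

  cycle_steady <- function(sat_time) {
    M <- as.numeric(network$M0)
    measured <- NULL
    converged <- FALSE
    for (i in seq_len(n_cycles)) {
      res <- run_cycle(M, sat_time)
      if (!is.null(measured) &&
          max(abs(res$measured - measured)) < tol) converged <- TRUE
      measured <- res$measured
      M <- res$M
      if (converged) break
    }
    if (!converged)
      warning("acquisition cycle did not reach steady state within ",
              n_cycles, " repetitions", call. = FALSE)
    list(measured = measured, converged = converged)
  }

  sat <- cycle_steady(t_sat)
  ref <- cycle_steady(0)
  meas_ratio <- sat$measured / ref$measured
  M0 <- as.numeric(network$M0)
  ideal <- c(
    progressive_signal(network$k_forward[["k1"]],
                       network$T1int[["PCr"]], t_sat),
    NA_real_,
    progressive_signal(network$k_forward[["k2"]],
                       network$T1int[["Pi"]], t_sat))
  dev <- meas_ratio / ideal - 1
  out <- c(PCr = dev[1], Pi = dev[3])
  attr(out, "converged") <- sat$converged && ref$converged
  # per-scan attenuations behind the ratio deviation, for diagnostics
  attr(out, "deficit_M0") <- c(PCr = 1 - ref$measured[1] / M0[1],
                               Pi = 1 - ref$measured[3] / M0[3])
  attr(out, "deficit_sat") <- c(PCr = 1 - sat$measured[1] / (M0[1] * ideal[1]),
                                Pi = 1 - sat$measured[3] / (M0[3] * ideal[3]))
  out
}
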