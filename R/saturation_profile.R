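#' Bloch simulation of the narrowband saturation pulse train
#'
#' Simulates a single spin (no exchange) through a train of amplitude-
#' modulated pulses with a hyperbolic-secant envelope
#' `B1(t) = B1max * sech(beta * (2t/Tp - 1))`, each followed by a crusher
#' that spoils all transverse magnetization, and returns the residual
#' longitudinal magnetization as a function of resonance offset.  This is
#' the saturation profile of the magnetization-transfer train: its full
#' width at half maximum characterises the selectivity of the gamma-ATP
#' irradiation, and the response at +/-2.5 ppm from the carrier quantifies
#' RF bleed-over onto the PCr peak.
#'
#' The envelope truncation `beta` is the one free shape parameter; the
#' default (`beta = 6.95`) is calibrated so that an 18-pulse (about 3 s)
#' train yields a saturation band of about 31 Hz FWHM and about 65 Hz full
#' width at 5% of maximum, with near-complete on-resonance saturation.
#'
#' @param scheme a [saturation_scheme()]; `n_pulses` pulses are simulated
#'   (at least 1).
#' @param offsets_Hz numeric grid of resonance offsets from the carrier
#'   (Hz); must span the saturation band.
#' @param beta dimensionless sech truncation factor.
#' @param n_steps_per_pulse time discretization within each pulse.
#' @param T1_s longitudinal relaxation during the pulse gaps (`Inf`
#'   disables recovery).
#' @param gamma_MHz_per_T gyromagnetic ratio over 2 pi for 31P.
#' @return object of class `saturation_profile`: list with `offsets_Hz`,
#'   `Mz` (residual longitudinal magnetization), `saturation` (`1 - Mz`),
#'   `fwhm_Hz`, `fw05_Hz` (full width at 5% of maximum saturation) and the
#'   scheme.
#' @examples
#' prof <- simulate_saturation_profile(
#'   saturation_scheme(n_pulses = 1), offsets_Hz = seq(-150, 150, 0.5))
#' prof$fwhm_Hz
#' @export
simulate_saturation_profile <- function(scheme,
                                        offsets_Hz = seq(-200, 200, by = 1),
                                        beta = 6.95, n_steps_per_pulse = 400,
                                        T1_s = Inf,
                                        gamma_MHz_per_T = 17.235) {
  stopifnot(inherits(scheme, "saturation_scheme"))
  np <- max(1L, scheme$n_pulses)
  Tp <- scheme$pulse_duration_s
  if (diff(range(offsets_Hz)) < 60)
    stop("offset grid must span the saturation band", call. = FALSE)

  # pulse amplitude in Hz: gamma/2pi [Hz/uT] * B1 [uT]
  nu1max <- gamma_MHz_per_T * scheme$B1max_uT
  dt <- Tp / n_steps_per_pulse
  tau <- (seq_len(n_steps_per_pulse) - 0.5) * dt
  nu1 <- nu1max / cosh(beta * (2 * tau / Tp - 1))

  no <- length(offsets_Hz)
  Mx <- numeric(no); My <- numeric(no); Mz <- rep(1, no)
  wz <- 2 * pi * offsets_Hz
  for (p in seq_len(np)) {
    for (s in seq_len(n_steps_per_pulse)) {
      wx <- 2 * pi * nu1[s]
      w <- sqrt(wx^2 + wz^2)
      phi <- w * dt
      nx <- wx / w; nz <- wz / w
      cphi <- cos(phi); sphi <- sin(phi)
      # Rodrigues rotation about the unit axis (nx, 0, nz); left-handed
      # precession sign conventions cancel in |Mz|, which is all we report
      dot <- nx * Mx + nz * Mz
      Mx2 <- Mx * cphi + (My * nz) * sphi + nx * dot * (1 - cphi)
      My2 <- My * cphi + (Mz * nx - Mx * nz) * sphi
      Mz2 <- Mz * cphi + (-My * nx) * sphi + nz * dot * (1 - cphi)
      Mx <- Mx2; My <- My2; Mz <- Mz2
    }
    # crusher gradient: spoil transverse magnetization
    Mx[] <- 0; My[] <- 0
    if (is.finite(T1_s) && p < np)
      Mz <- 1 + (Mz - 1) * exp(-scheme$pulse_gap_s / T1_s)
  }

  sat <- 1 - Mz
  out <- list(offsets_Hz = offsets_Hz, Mz = Mz, saturation = sat,
              fwhm_Hz = .profile_width(offsets_Hz, sat, 0.5),
              fw05_Hz = .profile_width(offsets_Hz, sat, 0.05),
              beta = beta, scheme = scheme)
  class(out) <- "saturation_profile"
  out
}

# full width of the saturation profile at `frac` of its maximum,
# by linear interpolation of the outermost crossings around the peak
.profile_width <- function(x, y, frac) {
  ymax <- max(y)
  if (ymax <= 0) return(NA_real_)
  lev <- frac * ymax
  above <- y >= lev
  if (!any(above) || all(above)) return(NA_real_)
  i1 <- which(above)[1]
  i2 <- rev(which(above))[1]
  left <- if (i1 == 1) x[1] else {
    x[i1 - 1] + (lev - y[i1 - 1]) / (y[i1] - y[i1 - 1]) * (x[i1] - x[i1 - 1])
  }
  right <- if (i2 == length(x)) x[i2] else {
    x[i2] + (lev - y[i2]) / (y[i2 + 1] - y[i2]) * (x[i2 + 1] - x[i2])
  }
  right - left
}

#' @export
print.saturation_profile <- function(x, ...) {
  cat("Saturation profile of the MT pulse train\n")
  cat(sprintf("  pulses: %d x %.5g ms, B1max %.3g uT, beta %.3g\n",
              max(1L, x$scheme$n_pulses), 1000 * x$scheme$pulse_duration_s,
              x$scheme$B1max_uT, x$beta))
  cat(sprintf("  FWHM: %.3g Hz   FW at 5%% max: %.3g Hz\n",
              x$fwhm_Hz, x$fw05_Hz))
  invisible(x)
}
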