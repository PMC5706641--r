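#' Metabolite concentration from an area ratio
#'
#' In fully relaxed 31P spectra areas are proportional to concentration, so a
#' metabolite concentration follows from its area ratio to gamma-ATP and the
#' assumed total ATP concentration (3 mM in the healthy human brain):
#' `[X] = (S_X / S_gATP) * [ATP]`.
#'
#' @param area_ratio dimensionless area ratio `S_X / S_gATP`, `>= 0`.
#' @param atp_conc assumed ATP concentration (mM), `> 0`.
#' @return concentration in mM.
#' @examples
#' concentration_from_ratio(1.22, 3)   # [PCr] ~ 3.7 mM
#' concentration_from_ratio(0.540, 3)  # [Pi]  ~ 1.6 mM
#' @export
concentration_from_ratio <- function(area_ratio, atp_conc = 3) {
  if (any(area_ratio < 0)) stop("area_ratio must be >= 0", call. = FALSE)
  if (atp_conc <= 0) stop("atp_conc must be > 0", call. = FALSE)
  area_ratio * atp_conc
}

#' Forward metabolic flux and unit conversion
#'
#' Forward flux of a pseudo-first-order reaction, `F = k * [substrate]`, in
#' mM/s, and its mass-specific equivalent in umol/g/min.  Since
#' mM = mmol/L = umol/mL, the conversion is `F * 60 / density` with the brain
#' tissue density in g/mL.
#'
#' @param k forward rate constant (1/s), `>= 0`.
#' @param conc substrate concentration (mM), `> 0`.
#' @param tissue_density tissue density (g/mL), default 1.1 for brain.
#' @return named numeric vector `c(flux_mM_s, flux_umol_g_min)`.
#' @examples
#' forward_flux(0.35, 3.7)  # CK flux at rest
#' @export
forward_flux <- function(k, conc, tissue_density = 1.1) {
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  if (conc <= 0 || tissue_density <= 0)
    stop("conc and tissue_density must be > 0", call. = FALSE)
  f <- k * conc
  c(flux_mM_s = f, flux_umol_g_min = f * 60 / tissue_density)
}

#' Convert a flux between mM/s and umol/g/min
#'
#' @param flux_mM_s flux in mM/s.
#' @param tissue_density tissue density (g/mL).
#' @return flux in umol/g/min.
#' @export
flux_to_umol_g_min <- function(flux_mM_s, tissue_density = 1.1) {
  flux_mM_s * 60 / tissue_density
}

#' @rdname flux_to_umol_g_min
#' @param flux_umol_g_min flux in umol/g/min.
#' @return flux in mM/s.
#' @export
flux_to_mM_s <- function(flux_umol_g_min, tissue_density = 1.1) {
  flux_umol_g_min * tissue_density / 60
}

#' Default Pi chemical-shift pH calibration
#'
#' Henderson-Hasselbalch titration constants for the pH-dependent chemical
#' shift of inorganic phosphate relative to PCr: apparent pKa and the
#' limiting acid/base shifts (ppm).  These are the classical in vivo values;
#' they can be overridden wherever a calibration argument is accepted, and
#' every report that uses them records them.
#'
#' @return list with `pKa`, `delta_acid_ppm`, `delta_base_ppm`.
#' @export
ph_calibration <- function() {
  list(pKa = 6.77, delta_acid_ppm = 3.29, delta_base_ppm = 5.68)
}

#' Intracellular pH from the PCr-Pi chemical-shift difference
#'
#' Modified Henderson-Hasselbalch relation
#' \deqn{pH = pKa + \log_{10}\frac{\delta - \delta_{acid}}
#'                                {\delta_{base} - \delta}}
#' applied to the observed shift difference between Pi and PCr (ppm).
#'
#' @param delta_ppm chemical-shift difference Pi relative to PCr (ppm); must
#'   lie strictly inside the calibration range.
#' @param calib calibration list as returned by [ph_calibration()].
#' @return pH (vectorized over `delta_ppm`).
#' @examples
#' ph_from_shift(4.795)  # ~ 7.00
#' @export
ph_from_shift <- function(delta_ppm, calib = ph_calibration()) {
  a <- calib$delta_acid_ppm; b <- calib$delta_base_ppm
  if (any(delta_ppm <= a) || any(delta_ppm >= b))
    stop(sprintf(
      "shift difference outside the pH calibration range (%.2f, %.2f) ppm",
      a, b), call. = FALSE)
  calib$pKa + log10((delta_ppm - a) / (b - delta_ppm))
}

#' @rdname ph_from_shift
#' @param pH pH value(s); inverse transform giving the Pi-PCr shift (ppm).
#' @export
shift_from_ph <- function(pH, calib = ph_calibration()) {
  a <- calib$delta_acid_ppm; b <- calib$delta_base_ppm
  x <- 10^(pH - calib$pKa)
  (a + b * x) / (1 + x)
}

#' Oxidative ATP synthesis flux implied by oxygen consumption
#'
#' Cross-check of the ATPase flux against PET oxygen metabolism: complete
#' oxidative phosphorylation produces `p_to_o2` ATP per O2 consumed, so the
#' ATP synthesis flux is `CMRO2 * P:O2`.
#'
#' @param cmro2 cerebral metabolic rate of O2 (umol/g/min), `> 0`.
#' @param p_to_o2 P:O2 ratio (dimensionless), default 6.
#' @return ATP synthesis flux (umol/g/min).
#' @examples
#' oxphos_flux_from_cmro2(1.71)  # ~ 10.3 umol/g/min
#' @export
oxphos_flux_from_cmro2 <- function(cmro2, p_to_o2 = 6) {
  if (cmro2 <= 0 || p_to_o2 <= 0)
    stop("cmro2 and p_to_o2 must be > 0", call. = FALSE)
  cmro2 * p_to_o2
}
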