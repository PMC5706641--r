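#' Three-pool chemical-exchange network for 31P saturation transfer
#'
#' Constructs the kinetic network underlying in vivo 31P magnetization
#' transfer: phosphocreatine (PCr) and inorganic phosphate (Pi) each exchange
#' magnetization with the gamma-phosphate of ATP through the creatine kinase
#' (CK, forward pseudo-first-order rate constant `k1`) and ATP synthase
#' (ATPase, rate constant `k2`) reactions.  Reverse rate constants are never
#' free parameters: they are derived from flux balance at equilibrium
#' (`k-1 = k1 * M0_PCr / M0_ATP`, `k-2 = k2 * M0_Pi / M0_ATP`), so the network
#' is fully specified by the forward rates, the equilibrium magnetizations and
#' the intrinsic longitudinal relaxation times.
#'
#' Equilibrium magnetizations `M0` are in arbitrary units proportional to
#' concentration; by convention the defaults use the gamma-ATP area as unity so
#' that `M0_PCr` and `M0_Pi` equal the PCr/gamma-ATP and Pi/gamma-ATP area
#' ratios of a fully relaxed, unsaturated spectrum.
#'
#' @param k1 forward CK rate constant, PCr -> ATP (1/s).
#' @param k2 forward ATPase rate constant, Pi -> ATP (1/s).
#' @param T1_PCr,T1_Pi,T1_ATP intrinsic longitudinal relaxation times (s),
#'   i.e. the relaxation each pool would show in the absence of exchange.
#'   `T1_ATP` only matters for the unclamped (free ATP) dynamics; all
#'   saturation-transfer estimators clamp ATP and are independent of it.
#' @param M0_PCr,M0_Pi,M0_ATP equilibrium magnetizations (area units).
#' @param conc_ATP assumed total ATP concentration (mM) used to convert area
#'   ratios to concentrations.
#' @return an object of class `exchange_network`: a list with elements
#'   `pools` (named character vector), `M0`, `T1int`, `k_forward`,
#'   `k_reverse` (derived) and `conc_ATP`.
#' @examples
#' net <- exchange_network(k1 = 0.35, k2 = 0.15)
#' net$k_reverse            # derived from flux balance
#' concentrations(net)      # mM, via the 3 mM ATP convention
#' @seealso [evolve_network()], [progressive_signal()], [fit_progressive()]
#' @export
exchange_network <- function(k1 = 0.35, k2 = 0.15,
                             T1_PCr = 5.1, T1_Pi = 3.0, T1_ATP = 1.0,
                             M0_PCr = 1.22, M0_Pi = 0.540, M0_ATP = 1.0,
                             conc_ATP = 3) {
  T1 <- c(PCr = T1_PCr, ATP = T1_ATP, Pi = T1_Pi)
  M0 <- c(PCr = M0_PCr, ATP = M0_ATP, Pi = M0_Pi)
  if (any(!is.finite(T1)) || any(T1 <= 0))
    stop("intrinsic T1 values must be finite and > 0", call. = FALSE)
  if (any(!is.finite(M0)) || any(M0 <= 0))
    stop("equilibrium magnetizations must be finite and > 0", call. = FALSE)
  if (k1 < 0 || k2 < 0)
    stop("forward rate constants must be >= 0", call. = FALSE)
  if (conc_ATP <= 0)
    stop("conc_ATP must be > 0", call. = FALSE)
  net <- list(
    pools = c("PCr", "ATP", "Pi"),
    M0 = M0,
    T1int = T1,
    k_forward = c(k1 = k1, k2 = k2),
    # flux balance: k1*M0_PCr = k-1*M0_ATP, k2*M0_Pi = k-2*M0_ATP
    k_reverse = c(k_1 = k1 * M0_PCr / M0_ATP, k_2 = k2 * M0_Pi / M0_ATP),
    conc_ATP = conc_ATP
  )
  class(net) <- "exchange_network"
  net
}

#' @export
print.exchange_network <- function(x, ...) {
  cat("Three-pool 31P exchange network (PCr <-> ATP <-> Pi)\n")
  cat(sprintf("  k1 (CK,    PCr->ATP): %.4g /s   k-1: %.4g /s\n",
              x$k_forward[["k1"]], x$k_reverse[["k_1"]]))
  cat(sprintf("  k2 (ATPase, Pi->ATP): %.4g /s   k-2: %.4g /s\n",
              x$k_forward[["k2"]], x$k_reverse[["k_2"]]))
  cat(sprintf("  T1int (s):  PCr %.3g  ATP %.3g  Pi %.3g\n",
              x$T1int[["PCr"]], x$T1int[["ATP"]], x$T1int[["Pi"]]))
  cat(sprintf("  M0 (area):  PCr %.3g  ATP %.3g  Pi %.3g\n",
              x$M0[["PCr"]], x$M0[["ATP"]], x$M0[["Pi"]]))
  invisible(x)
}

#' Metabolite concentrations implied by a network
#'
#' Areas are proportional to concentration, so `[X] = (M0_X / M0_ATP) * [ATP]`
#' with the assumed total ATP concentration stored in the network.
#'
#' @param network an [exchange_network()].
#' @return named numeric vector of concentrations (mM) for PCr, ATP, Pi.
#' @export
concentrations <- function(network) {
  stopifnot(inherits(network, "exchange_network"))
  network$M0 / network$M0[["ATP"]] * network$conc_ATP
}

#' Equilibrium fluxes of the CK and ATPase reactions
#'
#' Forward fluxes `F_CK = k1 * [PCr]` and `F_ATPase = k2 * [Pi]` in mM/s; at
#' equilibrium the reverse fluxes are equal by construction.
#'
#' @param network an [exchange_network()].
#' @return named numeric vector `c(F_CK, F_ATPase)` in mM/s.
#' @export
equilibrium_fluxes <- function(network) {
  conc <- concentrations(network)
  c(F_CK = network$k_forward[["k1"]] * conc[["PCr"]],
    F_ATPase = network$k_forward[["k2"]] * conc[["Pi"]])
}
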