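# Physical constants used throughout (CODATA 2018 values).
# Energies are handled in kcal/mol (enthalpies) and cal/(mol K) (entropies),
# the conventional units in the enzyme-kinetics literature.

#' Physical constants for transition-state-theory calculations
#'
#' @format A named list:
#' \describe{
#'   \item{kB_over_h}{Boltzmann constant / Planck constant, in s^-1 K^-1.}
#'   \item{R_cal}{Ideal gas constant in cal mol^-1 K^-1.}
#'   \item{R_kcal}{Ideal gas constant in kcal mol^-1 K^-1.}
#' }
#' @export
tst_constants <- list(
  kB_over_h = 1.380649e-23 / 6.62607015e-34, # 2.0836619e10 s^-1 K^-1
  R_cal     = 1.987204259,
  R_kcal    = 1.987204259e-3
)

#' Transition-state-theory (Eyring) rate constant
#'
#' Computes \eqn{k = \kappa (k_B T / h) e^{\Delta S^\ddagger / R}
#' e^{-\Delta H^\ddagger / (R T)}}.
#'
#' @param dH_kcal Activation enthalpy, kcal/mol.
#' @param dS_cal Activation entropy, cal/(mol K).
#' @param T_K Temperature(s) in kelvin; must be positive.
#' @param kappa Transmission coefficient (default 1).
#' @return Rate constant(s) in s^-1.
#' @export
#' @examples
#' eyring_rate(21.5, 11.5, 310.15)
eyring_rate <- function(dH_kcal, dS_cal, T_K, kappa = 1) {
  if (any(!is.finite(T_K)) || any(T_K <= 0)) {
    stop("temperature must be positive and finite (kelvin)")
  }
  kappa * tst_constants$kB_over_h * T_K *
    exp(dS_cal / tst_constants$R_cal) *
    exp(-dH_kcal * 1000 / (tst_constants$R_cal * T_K))
}
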