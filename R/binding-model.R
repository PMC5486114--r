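#' Equilibrium complex concentration from total concentrations
#'
#' Solves the 1:1 mass-balance quadratic
#' \deqn{[PL]^2 - (P_0 + L_0 + K_d)[PL] + P_0 L_0 = 0}
#' for the physically meaningful (smaller) root. Any consistent
#' concentration unit may be used for all three arguments; the result is in
#' the same unit.
#'
#' @param p0 total protein concentration (> 0).
#' @param l0 total ligand concentration (> 0).
#' @param kd dissociation constant (>= 0, same units). `kd = 0` is handled
#'   analytically as stoichiometric binding to avoid cancellation.
#' @return complex concentration `[PL]`, in `[0, min(p0, l0)]`.
#' @examples
#' solve_mass_balance(20, 80, 0)    # 20, stoichiometric limit
#' solve_mass_balance(10, 10, 10)   # (30 - sqrt(500))/2
#' @export
solve_mass_balance <- function(p0, l0, kd) {
  if (!is.numeric(p0) || !is.numeric(l0) || !is.numeric(kd))
    stopf("concentrations must be numeric")
  if (any(p0 <= 0) || any(l0 <= 0)) stopf("p0 and l0 must be > 0")
  if (any(kd < 0)) stopf("kd must be >= 0")
  if (all(is.infinite(kd))) return(0 * p0)
  ## stoichiometric limit: min(p0, l0) exactly
  s <- p0 + l0 + kd
  ## numerically stable smaller root: 2*p0*l0 / (s + sqrt(s^2 - 4 p0 l0))
  disc <- s^2 - 4 * p0 * l0
  disc[disc < 0] <- 0  # guard rounding for kd = 0, p0 = l0
  pl <- 2 * p0 * l0 / (s + sqrt(disc))
  pmin(pl, pmin(p0, l0))
}

#' Fraction of ligand bound at equilibrium
#'
#' `f_bound = [PL]/[L]0` from the exact 1:1 mass balance.
#'
#' @inheritParams solve_mass_balance
#' @return dimensionless fraction in `[0, min(1, p0/l0)]`.
#' @export
bound_fraction <- function(p0, l0, kd) {
  solve_mass_balance(p0, l0, kd) / l0
}

#' Two-site exchange kinetics at equilibrium
#'
#' Assembles the exchange quantities used by the selective-T1 estimator and
#' the relaxation-matrix simulator: complex concentration, bound fraction,
#' off-rate `koff = kd * kon` and bound-state lifetime `tau_bound = 1/koff`.
#' Interface units are micromolar; internal values are molar.
#'
#' @param p0_uM,l0_uM total protein / ligand concentration, micromolar.
#' @param kd_uM dissociation constant, micromolar.
#' @param kon association rate constant, 1/(M s). Default 1e8 (near
#'   diffusion limited) because typical ligand-observed studies report only
#'   Kd.
#' @return object of class `exchange_kinetics`: list with `kd`, `kon`,
#'   `koff`, `complex_conc` (M), `bound_fraction_ligand`, `bound_lifetime`
#'   (s), plus the molar totals `p0`, `l0`.
#' @export
exchange_kinetics <- function(p0_uM, l0_uM, kd_uM, kon = 1e8) {
  stopifnot(kon > 0)
  p0 <- uM_to_M(p0_uM); l0 <- uM_to_M(l0_uM); kd <- uM_to_M(kd_uM)
  pl <- solve_mass_balance(p0, l0, kd)
  koff <- kd * kon
  structure(list(
    p0 = p0, l0 = l0, kd = kd, kon = kon, koff = koff,
    complex_conc = pl,
    bound_fraction_ligand = pl / l0,
    bound_lifetime = if (koff > 0) 1 / koff else Inf
  ), class = "exchange_kinetics")
}

#' @export
print.exchange_kinetics <- function(x, ...) {
  cat("Two-site exchange kinetics\n")
  cat(sprintf("  Kd      : %.4g uM   kon: %.3g /M/s   koff: %.4g /s\n",
              M_to_uM(x$kd), x$kon, x$koff))
  cat(sprintf("  [PL]    : %.4g uM   f_bound(L): %.4g   tau_bound: %.3g s\n",
              M_to_uM(x$complex_conc), x$bound_fraction_ligand,
              x$bound_lifetime))
  invisible(x)
}

#' Sample conditions
#'
#' Container for the fixed experimental conditions of one sample.
#'
#' @param p0_uM protein concentration, micromolar.
#' @param l0_uM ligand concentration, micromolar (accepts `l0_mM` instead).
#' @param l0_mM ligand concentration, millimolar (alternative to `l0_uM`).
#' @param temperature_K temperature, kelvin.
#' @param spectrometer_MHz proton frequency, MHz.
#' @return object of class `sample_conditions` with molar concentrations and
#'   the angular Larmor frequency (`field_larmor_1H`, rad/s).
#' @export
sample_conditions <- function(p0_uM, l0_uM = NULL, l0_mM = NULL,
                              temperature_K = 298,
                              spectrometer_MHz = 600) {
  if (is.null(l0_uM) && is.null(l0_mM)) stopf("give l0_uM or l0_mM")
  l0 <- if (!is.null(l0_uM)) uM_to_M(l0_uM) else mM_to_M(l0_mM)
  if (p0_uM <= 0 || l0 <= 0) stopf("concentrations must be > 0")
  if (temperature_K <= 0 || spectrometer_MHz <= 0) stopf("invalid conditions")
  structure(list(
    protein_total_conc = uM_to_M(p0_uM),
    ligand_total_conc = l0,
    temperature = temperature_K,
    field_larmor_1H = larmor_from_mhz(spectrometer_MHz)
  ), class = "sample_conditions")
}
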