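#' STD amplification factor
#'
#' Scales an STD fraction by the ligand excess:
#' `STD-AF = STD * [L]0/[P]0`. Both concentrations must share a unit.
#'
#' @param std_fraction STD fraction(s), dimensionless.
#' @param l0,p0 total ligand / protein concentration, same unit; `p0 > 0`.
#' @return amplification factor, dimensionless.
#' @export
std_af <- function(std_fraction, l0, p0) {
  if (any(p0 <= 0)) stopf("p0 must be > 0")
  if (any(l0 < 0)) stopf("l0 must be >= 0")
  std_fraction * (l0 / p0)
}

#' STD-AF build-up initial slope
#'
#' Fits the saturating exponential to the amplification-factor-scaled
#' build-up curve and returns its initial slope `AF0 = a*b` (1/s). Because
#' the scaling is linear, this equals `(l0/p0) * STD0` of the unscaled
#' curve.
#'
#' @param curve a [buildup_curve] of STD fractions.
#' @inheritParams std_af
#' @return list with `af0` (1/s), the underlying `fit` (`buildup_fit` on
#'   the scaled curve) and the scale `l0/p0`.
#' @export
af_buildup_initial_slope <- function(curve, l0, p0) {
  stopifnot(inherits(curve, "buildup_curve"))
  if (p0 <= 0) stopf("p0 must be > 0")
  scaled <- curve
  scaled$std_fractions <- std_af(curve$std_fractions, l0, p0)
  t <- scaled$saturation_times; y <- scaled$std_fractions
  if (length(unique(t)) < 3) stopf("need >= 3 distinct time points")
  f <- fit_sat_exp(t, y, weights = curve$sigma)
  fit <- structure(list(std_max = f$a, k_sat = f$b, std0 = f$a * f$b,
                        residual_norm = f$residual_norm,
                        parameter_uncertainties = f$se,
                        proton_label = curve$proton_label,
                        ligand_id = curve$ligand_id),
                   class = "buildup_fit")
  list(af0 = fit$std0, fit = fit, excess = l0 / p0)
}

#' STD-AF titration
#'
#' A binding isotherm: STD-AF initial slopes at several ligand
#' concentrations and fixed protein concentration.
#'
#' @param ligand_concs_mM ligand concentrations, millimolar, strictly
#'   positive and distinct.
#' @param af0_values STD-AF0 values (1/s), one per concentration, >= 0.
#' @param protein_conc_uM fixed protein concentration, micromolar.
#' @param af0_se optional standard errors on af0 for weighted fitting.
#' @return object of class `af_titration`.
#' @export
af_titration <- function(ligand_concs_mM, af0_values, protein_conc_uM,
                         af0_se = NULL) {
  L <- as.numeric(ligand_concs_mM); y <- as.numeric(af0_values)
  if (length(L) != length(y)) stopf("lengths differ")
  if (any(L <= 0) || anyDuplicated(L)) stopf("concentrations must be positive and distinct")
  if (any(y < 0)) stopf("af0 must be >= 0")
  structure(list(ligand_concs = L, af0_values = y,
                 protein_conc = protein_conc_uM, af0_se = af0_se),
            class = "af_titration")
}

#' Fit a Langmuir isotherm to an STD-AF titration
#'
#' Least-squares fit of
#' \deqn{AF_0(L) = AF_{0,max} \frac{L}{L + IC_{50}}}
#' The half-saturation concentration is reported as IC50, following common
#' ligand-observed usage where IC50 and Kd are used interchangeably for
#' this single-site isotherm.
#'
#' @param titration an [af_titration] (concentrations in mM).
#' @param weighted if `TRUE` and `af0_se` is present, weight points by
#'   `1/se^2`. Off by default (no error model is usually available).
#' @return object of class `langmuir_fit`: `af0_max` (1/s), `ic50` (mM),
#'   `residual_norm`, asymptotic standard errors in
#'   `parameter_uncertainties`.
#' @examples
#' L <- c(0.4, 0.8, 1.6, 3.2, 6.4)
#' ti <- af_titration(L, 10 * L / (L + 1.7), 19)
#' fit_langmuir(ti)$ic50   # 1.7
#' @export
fit_langmuir <- function(titration, weighted = FALSE) {
  stopifnot(inherits(titration, "af_titration"))
  L <- titration$ligand_concs; y <- titration$af0_values
  if (length(unique(L)) < 3) stopf("need >= 3 distinct concentrations")
  w <- rep(1, length(y))
  if (weighted && !is.null(titration$af0_se)) w <- 1 / titration$af0_se^2
  ## the plateau is linear in the data for fixed IC50: profile it out and
  ## solve the remaining 1-D problem on a log-spaced IC50 axis
  prof_amax <- function(ic) {
    x <- L / (L + ic)
    max(0, sum(w * y * x) / sum(w * x^2))
  }
  sse <- function(ic) {
    x <- L / (L + ic)
    sum(w * (y - prof_amax(ic) * x)^2)
  }
  ic50 <- profiled_min(sse, min(L) * 1e-4, max(L) * 1e4)
  amax <- prof_amax(ic50)
  if (!is.finite(ic50) || amax <= 0)
    stopf("Langmuir fit failed: degenerate isotherm (all af0 ~ 0?)")
  x <- L / (L + ic50)
  resid <- y - amax * x
  J <- cbind(amax = x, ic50 = -amax * L / (L + ic50)^2)
  se <- jac_se(J, resid, w, 2)
  if (ic50 > max(L))
    warnf("isotherm not saturating: fitted IC50 (%.3g mM) exceeds the largest concentration (%.3g mM); confidence interval will be wide",
          ic50, max(L))
  structure(list(af0_max = amax, ic50 = ic50,
                 residual_norm = sqrt(sum(resid^2)),
                 parameter_uncertainties = c(af0_max = se[1], ic50 = se[2])),
            class = "langmuir_fit")
}

#' @export
print.langmuir_fit <- function(x, ...) {
  se <- x$parameter_uncertainties["ic50"]
  cat(sprintf("Langmuir isotherm fit: AF0max = %.4g /s, IC50 = %.4g +/- %.2g mM\n",
              x$af0_max, x$ic50, se))
  invisible(x)
}

#' Full STD-AF IC50 pipeline from per-concentration build-up curves
#'
#' Convenience wrapper: computes the AF0 initial slope of each
#' concentration's build-up curve, assembles the isotherm and fits the
#' Langmuir equation.
#'
#' @param curves named list of [buildup_curve]s; names are ligand
#'   concentrations in mM (or pass `ligand_concs_mM`).
#' @param p0_uM fixed protein concentration, micromolar.
#' @param ligand_concs_mM optional explicit concentration vector.
#' @return list with the `langmuir_fit` (`fit`), the [af_titration]
#'   (`titration`) and per-concentration AF0 values.
#' @export
std_af_ic50 <- function(curves, p0_uM, ligand_concs_mM = NULL) {
  if (is.null(ligand_concs_mM)) ligand_concs_mM <- as.numeric(names(curves))
  if (any(is.na(ligand_concs_mM))) stopf("curve names must be concentrations in mM")
  af0 <- mapply(function(cv, L) {
    af_buildup_initial_slope(cv, l0 = mM_to_M(L), p0 = uM_to_M(p0_uM))$af0
  }, curves, ligand_concs_mM)
  ti <- af_titration(ligand_concs_mM, af0, p0_uM)
  list(fit = fit_langmuir(ti), titration = ti, af0 = af0)
}
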