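#' Inversion-recovery trace
#'
#' Signal intensity of a selectively inverted ligand resonance versus
#' recovery delay, at one ligand concentration.
#'
#' @param recovery_delays delays in seconds, >= 0, strictly increasing,
#'   at least 4 points.
#' @param intensities signal intensities, arbitrary units.
#' @param ligand_conc_uM,protein_conc_uM sample concentrations, micromolar.
#' @param ligand_id identifier carried through to reports.
#' @return object of class `ir_trace`.
#' @export
ir_trace <- function(recovery_delays, intensities,
                     ligand_conc_uM = NA_real_, protein_conc_uM = NA_real_,
                     ligand_id = "ligand") {
  t <- as.numeric(recovery_delays); y <- as.numeric(intensities)
  if (length(t) != length(y)) stopf("lengths differ")
  if (length(t) < 4) stopf("need >= 4 delay points")
  if (any(t < 0) || any(diff(t) <= 0))
    stopf("delays must be >= 0 and strictly increasing")
  structure(list(recovery_delays = t, intensities = y,
                 ligand_conc = ligand_conc_uM, protein_conc = protein_conc_uM,
                 ligand_id = ligand_id),
            class = "ir_trace")
}

#' Fit an inversion-recovery trace for the selective T1
#'
#' Three-parameter exponential recovery
#' \deqn{f(t) = I_0\,[1 - a \exp(-t/T_1)]}
#' with the inversion efficiency `a` fitted (ideal inversion gives a = 2,
#' real inversions are imperfect). The null point of the recovery sits at
#' `t = T1 * ln(a)`.
#'
#' @param trace an [ir_trace]. Delays should span roughly 2 x T1 or more.
#' @return object of class `t1_fit`: `i0`, `amp` (a), `t1_sel` (s),
#'   `residual_norm`, `parameter_uncertainties`.
#' @export
fit_inversion_recovery <- function(trace) {
  stopifnot(inherits(trace, "ir_trace"))
  t <- trace$recovery_delays; y <- trace$intensities
  ## for fixed T1 the model y = i0 - (i0 a) e^{-t/T1} is linear in
  ## (i0, c = i0 a): profile both out, 1-D search over T1
  lin_coef <- function(t1) {
    e <- exp(-t / t1)
    stats::lm.fit(cbind(1, -e), y)$coefficients
  }
  sse <- function(t1) {
    e <- exp(-t / t1)
    cf <- lin_coef(t1)
    if (any(!is.finite(cf))) return(Inf)
    sum((y - cf[1] + cf[2] * e)^2)
  }
  dt <- diff(t)
  t1 <- profiled_min(sse, max(min(dt[dt > 0]) / 100, 1e-6), 100 * max(t))
  cf <- lin_coef(t1)
  i0 <- unname(cf[1]); amp <- unname(cf[2] / cf[1])
  if (!is.finite(i0) || !is.finite(amp) || i0 == 0)
    stopf("inversion-recovery fit failed: degenerate trace")
  if (amp < 0) warnf("fitted inversion efficiency a < 0: no inversion seen")
  if (t1 > max(t))
    warnf("fitted T1 (%.3g s) exceeds the longest delay; extend the delay list",
          t1)
  e <- exp(-t / t1)
  resid <- y - i0 * (1 - amp * e)
  J <- cbind(i0 = 1 - amp * e, a = -i0 * e,
             t1 = -i0 * amp * e * t / t1^2)
  se <- jac_se(J, resid, rep(1, length(y)), 3)
  structure(list(i0 = i0, amp = amp, t1_sel = t1,
                 residual_norm = sqrt(sum(resid^2)),
                 parameter_uncertainties = c(i0 = unname(se[1]),
                                             amp = unname(se[2]),
                                             t1_sel = unname(se[3])),
                 ligand_conc = trace$ligand_conc,
                 protein_conc = trace$protein_conc,
                 ligand_id = trace$ligand_id),
            class = "t1_fit")
}

#' @export
print.t1_fit <- function(x, ...) {
  cat(sprintf("Inversion-recovery fit [%s]: I0 = %.4g, a = %.4g, T1sel = %.4g s\n",
              x$ligand_id, x$i0, x$amp, x$t1_sel))
  invisible(x)
}

#' Observed selective T1 under two-site fast exchange
#'
#' Forward model for the observed ligand relaxation time:
#' \deqn{1/T_{1,obs} = 1/T_{1,free} + f_{bound}/(T_{1,bound} + \tau_{bound})}
#' with `f_bound` from the exact 1:1 mass balance, or from the dilute-limit
#' linearization `f_bound = p0/(l0 + kd)` when `approx = "linear"` (the form
#' under which `[P]0 T1obs = ([L]0 + Kd)(T1bound + tau_bound)` holds
#' exactly).
#'
#' @param l0,p0,kd concentrations in a shared unit (e.g. micromolar).
#' @param t1_free free-ligand selective T1, seconds (`Inf` drops the free
#'   relaxation term).
#' @param t1_bound bound-state T1, seconds.
#' @param tau_bound bound-state lifetime, seconds.
#' @param approx `"exact"` (default) or `"linear"` bound fraction.
#' @return observed T1 in seconds.
#' @export
model_t1obs <- function(l0, p0, kd, t1_free, t1_bound, tau_bound,
                        approx = c("exact", "linear")) {
  approx <- match.arg(approx)
  if (any(t1_bound + tau_bound <= 0)) stopf("t1_bound + tau_bound must be > 0")
  if (any(t1_free <= 0)) stopf("t1_free must be > 0")
  fb <- if (approx == "linear") p0 / (l0 + kd) else bound_fraction(p0, l0, kd)
  rate <- ifelse(is.infinite(t1_free), 0, 1 / t1_free) +
    fb / (t1_bound + tau_bound)
  1 / rate
}

#' Selective-T1 titration
#'
#' @param ligand_concs_uM ligand concentrations, micromolar.
#' @param t1_obs_s observed selective T1 per concentration, seconds.
#' @param protein_conc_uM fixed protein concentration, micromolar.
#' @param t1_free_s optional free-ligand T1 (ligand-only reference).
#' @return object of class `t1_titration`.
#' @export
t1_titration <- function(ligand_concs_uM, t1_obs_s, protein_conc_uM,
                         t1_free_s = NULL) {
  L <- as.numeric(ligand_concs_uM); y <- as.numeric(t1_obs_s)
  if (length(L) != length(y)) stopf("lengths differ")
  if (any(L <= 0) || any(y <= 0)) stopf("concentrations and T1 must be > 0")
  structure(list(ligand_concs = L, t1_obs = y,
                 protein_conc = protein_conc_uM, t1_free = t1_free_s),
            class = "t1_titration")
}

#' IC50 from a selective-T1 titration
#'
#' Under fast exchange and ligand excess, `[P]0 * T1obs` is linear in
#' `[L]0`:
#' \deqn{[P]_0 T_{1,obs} = ([L]_0 + IC_{50})(T_{1,bound} + \tau_{bound})}
#' so an ordinary least-squares line through `([L]0, [P]0 T1obs)` crosses
#' the x axis at `-IC50`. The default follows this relation verbatim;
#' `subtract_free = TRUE` first removes the free-ligand relaxation rate
#' using the titration's `t1_free` reference.
#'
#' @param titration a [t1_titration] (micromolar concentrations).
#' @param subtract_free replace `1/T1obs` by `1/T1obs - 1/T1free` before
#'   the line fit (requires `t1_free` in the titration).
#' @return list with `ic50` (micromolar), `se` (delta-method standard
#'   error), `slope`, `intercept`, `r_squared`, and the underlying `lm`
#'   fit.
#' @export
estimate_ic50_t1 <- function(titration, subtract_free = FALSE) {
  stopifnot(inherits(titration, "t1_titration"))
  L <- titration$ligand_concs
  if (length(unique(L)) < 3) stopf("need >= 3 distinct concentrations")
  t1 <- titration$t1_obs
  if (subtract_free) {
    if (is.null(titration$t1_free)) stopf("subtract_free requires t1_free")
    rate <- 1 / t1 - 1 / titration$t1_free
    if (any(rate <= 0)) stopf("free-rate subtraction leaves non-positive rates")
    t1 <- 1 / rate
  }
  y <- titration$protein_conc * t1
  fit <- stats::lm(y ~ L)
  b <- unname(stats::coef(fit))  # intercept, slope
  if (b[2] <= 0) stopf("no binding signal: fitted slope is not positive")
  ic50 <- b[1] / b[2]
  ## vcov by hand: vcov(lm) warns on perfect (zero-residual) fits
  X <- cbind(1, L)
  s2 <- sum(stats::resid(fit)^2) / (length(L) - 2)
  V <- s2 * solve(crossprod(X))
  se <- sqrt(V[1, 1] / b[2]^2 + b[1]^2 * V[2, 2] / b[2]^4 -
               2 * b[1] * V[1, 2] / b[2]^3)
  if (ic50 < -1e-9 * max(L))  # ignore rounding-level negatives
    warnf("negative IC50 (%.3g): x-intercept is positive", ic50)
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  list(ic50 = ic50, se = se, slope = b[2], intercept = b[1],
       r_squared = r2, fit = fit)
}

#' Selective-T1 IC50 pipeline from inversion-recovery traces
#'
#' Fits each trace for its observed T1 and feeds the titration line fit.
#'
#' @param traces list of [ir_trace]s sharing a protein concentration,
#'   one per ligand concentration.
#' @param subtract_free see [estimate_ic50_t1].
#' @param t1_free_s optional free-ligand reference T1.
#' @return list with `ic50`, `se`, per-concentration `t1_obs`, and the
#'   titration object.
#' @export
t1_ic50 <- function(traces, subtract_free = FALSE, t1_free_s = NULL) {
  fits <- lapply(traces, fit_inversion_recovery)
  L <- vapply(fits, function(f) f$ligand_conc, numeric(1))
  p0 <- unique(vapply(fits, function(f) f$protein_conc, numeric(1)))
  if (length(p0) != 1 || !is.finite(p0))
    stopf("traces must share one finite protein concentration")
  ti <- t1_titration(L, vapply(fits, function(f) f$t1_sel, numeric(1)),
                     p0, t1_free_s)
  est <- estimate_ic50_t1(ti, subtract_free = subtract_free)
  c(est[c("ic50", "se", "slope", "intercept", "r_squared")],
    list(t1_obs = ti$t1_obs, titration = ti, t1_fits = fits))
}
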