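#' Noise model for synthetic data
#'
#' Additive Gaussian noise, with `sigma` read as a fraction of the local
#' signal (`relative = TRUE`, the default: spectrometer-style noise scales
#' with peak height here) or as an absolute standard deviation.
#'
#' @param sigma non-negative noise level. Defaults used by the generators:
#'   2\% for STD-type data, 1\% for T1 data.
#' @param relative interpret `sigma` relative to the signal.
#' @param seed integer seed; identical seeds give identical streams.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(sigma = 0, relative = TRUE, seed = 1L) {
  if (sigma < 0) stopf("sigma must be >= 0")
  structure(list(sigma = sigma, relative = relative, seed = as.integer(seed)),
            class = "noise_model")
}

apply_noise <- function(values, noise) {
  if (is.null(noise) || noise$sigma == 0) return(values)
  with_seed(noise$seed, {
    sd <- if (noise$relative) noise$sigma * abs(values) else
      rep(noise$sigma, length(values))
    values + stats::rnorm(length(values), 0, sd)
  })
}

as_noise <- function(sigma, seed, relative = TRUE) {
  if (inherits(sigma, "noise_model")) sigma else
    noise_model(sigma, relative = relative, seed = seed)
}

#' Generate an STD build-up curve
#'
#' Mono-exponential model values `a(1 - exp(-b t))` plus optional Gaussian
#' noise, clipped to `[0, 1]`.
#'
#' @param a asymptotic STD maximum in `[0, 1]`.
#' @param b build-up rate, 1/s.
#' @param times saturation times, seconds (default the 0.5--4 s ladder).
#' @param sigma relative noise level or a [noise_model] (default 0).
#' @param seed integer seed used when `sigma` is numeric.
#' @param proton_label,ligand_id identifiers.
#' @return a [buildup_curve].
#' @export
gen_buildup <- function(a, b, times = c(0.5, 1, 2, 3, 4), sigma = 0,
                        seed = 1L, proton_label = "H", ligand_id = "ligand") {
  if (a < 0 || a > 1) stopf("a must be in [0, 1]")
  if (b <= 0) stopf("b must be > 0")
  y <- a * (1 - exp(-b * times))
  y <- pmin(1, pmax(0, apply_noise(y, as_noise(sigma, seed))))
  buildup_curve(times, y, proton_label = proton_label, ligand_id = ligand_id)
}

#' Generate an STD-AF titration
#'
#' Langmuir model `af0_max * L/(L + ic50)` on a concentration ladder, with
#' optional relative Gaussian noise. The default ladder is a geometric
#' series bracketing the IC50 two octaves each way, which keeps both
#' isotherm parameters identifiable.
#'
#' @param af0_max plateau AF0, 1/s.
#' @param ic50_mM half-saturation concentration, millimolar.
#' @param ladder_mM ligand concentrations, millimolar.
#' @param protein_conc_uM fixed protein concentration, micromolar.
#' @param sigma,seed noise controls as in [gen_buildup] (STD-type default
#'   would be 0.02).
#' @return an [af_titration].
#' @export
gen_af_titration <- function(af0_max, ic50_mM,
                             ladder_mM = ic50_mM * 2^(-2:2),
                             protein_conc_uM = 19, sigma = 0, seed = 1L) {
  if (af0_max <= 0 || ic50_mM <= 0) stopf("af0_max and ic50 must be > 0")
  y <- af0_max * ladder_mM / (ladder_mM + ic50_mM)
  y <- pmax(0, apply_noise(y, as_noise(sigma, seed)))
  af_titration(ladder_mM, y, protein_conc_uM)
}

#' Generate per-concentration STD build-up curves for an AF titration
#'
#' The route the amplification-factor pipeline actually consumes: for each
#' ladder concentration the underlying STD0 is set so that the AF-scaled
#' initial slope follows the Langmuir isotherm, and a full build-up curve
#' is emitted with fixed saturation rate `b`.
#'
#' @inheritParams gen_af_titration
#' @param b build-up rate shared across concentrations, 1/s.
#' @param times saturation times, seconds.
#' @return named list of [buildup_curve]s; names are concentrations in mM.
#' @export
gen_af_buildup_series <- function(af0_max, ic50_mM,
                                  ladder_mM = ic50_mM * 2^(-2:2),
                                  protein_conc_uM = 19, b = 1,
                                  times = c(0.5, 1, 2, 3, 4),
                                  sigma = 0, seed = 1L) {
  curves <- lapply(seq_along(ladder_mM), function(k) {
    L <- ladder_mM[k]
    af0 <- af0_max * L / (L + ic50_mM)
    std0 <- af0 / (mM_to_M(L) / uM_to_M(protein_conc_uM))
    a <- std0 / b
    if (a > 1) stopf("ladder point %g mM needs STDmax > 1; raise b or the excess", L)
    gen_buildup(a, b, times = times, sigma = sigma, seed = seed + k,
                ligand_id = sprintf("L%gmM", L))
  })
  names(curves) <- as.character(ladder_mM)
  curves
}

#' Generate a selective-T1 titration
#'
#' Two modes. `"linear"` reproduces the estimator's own model exactly:
#' `T1obs = ([L]0 + IC50)(T1bound + tau_bound)/[P]0` (the infinite-T1free,
#' dilute-limit form under which the x-intercept equals -IC50).
#' `"full"` uses the complete two-site fast-exchange expression with
#' finite `t1_free` and the exact mass balance, so estimates from it carry
#' the linearization bias.
#'
#' @param ic50_uM generating IC50 (= Kd), micromolar.
#' @param t1b_plus_tau `T1bound + tau_bound`, seconds (default 0.1 s, a
#'   plausible bound-state value for a small saccharide on a 16 kDa
#'   protein).
#' @param ladder_uM ligand concentrations, micromolar; default the
#'   1:4 ... 1:32 ladder 80--640 uM.
#' @param protein_conc_uM protein concentration, micromolar (default 20).
#' @param mode `"linear"` or `"full"`.
#' @param t1_free free-ligand T1 for full mode, seconds.
#' @param sigma,seed noise on T1obs, relative (T1-type default would be
#'   0.01).
#' @param output `"table"` returns a [t1_titration]; `"traces"` returns
#'   inversion-recovery traces (`i0 = 1`, `amp = 2`) at `delays`.
#' @param delays recovery delays for trace output, seconds.
#' @return a [t1_titration] or a list of [ir_trace]s.
#' @export
gen_t1_titration <- function(ic50_uM, t1b_plus_tau = 0.1,
                             ladder_uM = c(80, 160, 320, 480, 640),
                             protein_conc_uM = 20,
                             mode = c("linear", "full"), t1_free = 3,
                             sigma = 0, seed = 1L,
                             output = c("table", "traces"),
                             delays = c(0.01, 0.05, 0.1, 0.25, 0.5,
                                        1, 2, 4, 8, 16)) {
  mode <- match.arg(mode); output <- match.arg(output)
  if (ic50_uM < 0) stopf("ic50 must be >= 0")
  t1obs <- if (mode == "linear") {
    (ladder_uM + ic50_uM) * t1b_plus_tau / protein_conc_uM
  } else {
    model_t1obs(ladder_uM, protein_conc_uM, ic50_uM, t1_free = t1_free,
                t1_bound = t1b_plus_tau, tau_bound = 0, approx = "exact")
  }
  t1obs <- apply_noise(t1obs, as_noise(sigma, seed))
  if (any(t1obs <= 0)) stopf("noise drove a T1obs non-positive; lower sigma")
  if (output == "table")
    return(t1_titration(ladder_uM, t1obs, protein_conc_uM,
                        t1_free_s = if (mode == "full") t1_free else NULL))
  lapply(seq_along(ladder_uM), function(k) {
    y <- 1 * (1 - 2 * exp(-delays / t1obs[k]))
    ir_trace(delays, y, ligand_conc_uM = ladder_uM[k],
             protein_conc_uM = protein_conc_uM)
  })
}

#' Generate a toy ligand-protein spin system
#'
#' Random but physical proton coordinates: protein protons packed around
#' the origin, ligand protons seeded within 2--6 Angstrom of a protein
#' proton (inside the usual cutoff shell), all pairwise distances at least
#' `min_dist`. Reproducible by seed; all protein protons are marked
#' saturated by default (override via the returned object).
#'
#' @param n_ligand,n_protein proton counts, >= 1.
#' @param seed integer seed.
#' @param min_dist minimum allowed pairwise distance, Angstrom
#'   (default 1.7, roughly a van der Waals H...H contact).
#' @param max_attempts rejection-sampling budget per proton.
#' @return a [spin_system].
#' @export
gen_toy_complex <- function(n_ligand, n_protein, seed = 1L,
                            min_dist = 1.7, max_attempts = 2000) {
  if (n_ligand < 1 || n_protein < 1) stopf("counts must be >= 1")
  with_seed(seed, {
    box <- 2.5 * (n_ligand + n_protein)^(1/3) + 2
    pts <- matrix(NA_real_, n_ligand + n_protein, 3)
    place <- function(k, propose) {
      for (i in seq_len(max_attempts)) {
        p <- propose()
        if (k == 1) return(p)
        d2 <- rowSums(sweep(pts[seq_len(k - 1), , drop = FALSE], 2, p)^2)
        if (min(d2) >= min_dist^2) return(p)
      }
      stopf("packing failed after %d attempts; reduce counts or min_dist",
            max_attempts)
    }
    for (k in seq_len(n_protein))
      pts[k, ] <- place(k, function() stats::runif(3, -box / 2, box / 2))
    for (k in n_protein + seq_len(n_ligand)) {
      anchor <- pts[sample.int(n_protein, 1), ]
      pts[k, ] <- place(k, function() {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        anchor + stats::runif(1, max(2, min_dist), 6) * u
      })
    }
    ord <- c(n_protein + seq_len(n_ligand), seq_len(n_protein))
    spin_system(
      labels = c(paste0("L", seq_len(n_ligand)),
                 paste0("P", seq_len(n_protein))),
      owner = rep(c("ligand", "protein"), c(n_ligand, n_protein)),
      xyz_bound = pts[ord, , drop = FALSE],
      saturated = rep(c(FALSE, TRUE), c(n_ligand, n_protein)))
  })
}
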