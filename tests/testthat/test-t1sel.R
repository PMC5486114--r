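test_that("noise-free inversion-recovery fits recover the generator", {
  delays <- c(0.01, 0.1, 0.3, 0.7, 1.5, 3, 6)
  cases <- list(c(1, 2, 1), c(5, 1.8, 0.4), c(1, 2, 2.2))
  for (p in cases) {
    y <- p[1] * (1 - p[2] * exp(-delays / p[3]))
    f <- fit_inversion_recovery(ir_trace(delays, y))
    expect_equal(f$i0, p[1], tolerance = 1e-6)
    expect_equal(f$amp, p[2], tolerance = 1e-6)
    expect_equal(f$t1_sel, p[3], tolerance = 1e-6)
  }
})

test_that("recovery null point sits at t = T1 ln(a)", {
  t1 <- 0.8; a <- 2
  tnull <- t1 * log(a)
  expect_equal(1 * (1 - a * exp(-tnull / t1)), 0)
  # and the fit pins it: model value at T1*ln(a_hat) of the fit is ~0
  delays <- c(0.01, 0.1, 0.3, 0.7, 1.5, 3, 6)
  f <- fit_inversion_recovery(ir_trace(delays, 1 - a * exp(-delays / t1)))
  expect_equal(f$i0 * (1 - f$amp * exp(-(f$t1_sel * log(f$amp)) / f$t1_sel)),
               0, tolerance = 1e-8)
})

test_that("IR optimizer beats a parameter grid on a noisy seeded trace", {
  delays <- c(0.01, 0.05, 0.1, 0.25, 0.5, 1, 2, 4, 8)
  set.seed(31)
  y <- (1 - 2 * exp(-delays / 0.9)) * (1 + rnorm(length(delays), 0, 0.01))
  f <- fit_inversion_recovery(ir_trace(delays, y))
  sse_fit <- f$residual_norm^2
  ## grid over (a, t1) at the fitted i0 plus grid over (i0, t1) at a = 2
  sse_grid <- min(
    grid_sse(delays, y, function(t, a, t1) f$i0 * (1 - a * exp(-t / t1)),
             c(1.5, 2.5), c(0.2, 3), n = 200),
    grid_sse(delays, y, function(t, i0, t1) i0 * (1 - 2 * exp(-t / t1)),
             c(0.8, 1.2), c(0.2, 3), n = 200))
  expect_lte(sse_fit, sse_grid + 1e-12)
})

test_that("model_t1obs limits and the paper-style linear relation", {
  # no binding: T1obs = T1free
  expect_equal(model_t1obs(80, 20, Inf, t1_free = 1.2, t1_bound = 0.1,
                           tau_bound = 0), 1.2)
  # infinite T1free + linear f_bound reproduces the linear relation exactly
  expect_equal(model_t1obs(80, 20, 49.2, t1_free = Inf, t1_bound = 0.1,
                           tau_bound = 0, approx = "linear"),
               (80 + 49.2) * 0.1 / 20, tolerance = 1e-12)
  # the linearization emerges from the exact model as l0/p0 grows
  err <- vapply(c(10, 100, 1000), function(scale) {
    L <- 80 * scale
    exact <- model_t1obs(L, 20, 49.2, Inf, 0.1, 0)
    lin <- (L + 49.2) * 0.1 / 20
    abs(exact - lin) / lin
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_error(model_t1obs(80, 20, 10, t1_free = 0, t1_bound = 0.1,
                           tau_bound = 0), "t1_free")
})

test_that("IC50 line fit: exact recovery, origin line, error branches", {
  y_line <- 0.002 * (paper_t1_ladder + 49.2)     # [P]0*T1obs, s*uM/uM
  ti <- t1_titration(paper_t1_ladder, y_line / 20, 20)
  est <- estimate_ic50_t1(ti)
  expect_equal(est$ic50, 49.2, tolerance = 1e-9)
  expect_equal(est$r_squared, 1, tolerance = 1e-12)
  # line through origin -> ic50 = 0
  ti0 <- t1_titration(paper_t1_ladder, 0.002 * paper_t1_ladder / 20, 20)
  expect_equal(estimate_ic50_t1(ti0)$ic50, 0, tolerance = 1e-9)
  # negative slope -> no binding signal
  tin <- t1_titration(paper_t1_ladder, rev(paper_t1_ladder) / 100, 20)
  expect_error(estimate_ic50_t1(tin), "no binding signal")
})

test_that("unit covariance: rescaling concentrations rescales IC50 only", {
  ti_uM <- gen_t1_titration(84.7, sigma = 0.01, seed = 8)
  est_uM <- estimate_ic50_t1(ti_uM)
  ti_mM <- t1_titration(ti_uM$ligand_concs / 1000, ti_uM$t1_obs,
                        ti_uM$protein_conc / 1000)
  est_mM <- estimate_ic50_t1(ti_mM)
  expect_equal(est_mM$ic50 * 1000, est_uM$ic50, tolerance = 1e-9)
  expect_equal(est_mM$r_squared, est_uM$r_squared, tolerance = 1e-12)
})

test_that("full-pipeline round trip: traces -> T1 fits -> IC50", {
  traces <- gen_t1_titration(49.2, output = "traces", sigma = 0)
  res <- t1_ic50(traces)
  expect_equal(res$ic50, 49.2, tolerance = 1e-6)
})

test_that("linearization bias is monotone in 1/t1_free (documented, not an error)", {
  bias <- vapply(c(200, 20, 5, 2), function(t1f) {
    ti <- gen_t1_titration(84.7, mode = "full", t1_free = t1f, sigma = 0)
    abs(estimate_ic50_t1(ti)$ic50 - 84.7)
  }, numeric(1))
  expect_true(all(diff(bias) > 0))
})

test_that("subtract-free mode removes the free-relaxation bias", {
  ti <- gen_t1_titration(84.7, mode = "full", t1_free = 2, sigma = 0)
  biased <- estimate_ic50_t1(ti)$ic50
  corrected <- estimate_ic50_t1(ti, subtract_free = TRUE)$ic50
  # full-model f_bound is exact, not linear, so correction is not perfect,
  # but it must beat the verbatim estimator by a wide margin
  expect_lt(abs(corrected - 84.7), abs(biased - 84.7) / 2)
})
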