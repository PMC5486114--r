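omega600 <- larmor_from_mhz(600)

test_that("spectral densities: values, limits, monotonicity", {
  tau <- 22e-9
  expect_equal(spectral_density(0, tau), tau)
  expect_equal(spectral_density(1 / tau, tau), tau / 2)
  om <- seq(0, 1e10, length.out = 50)
  expect_true(all(diff(spectral_density(om, tau)) < 0))
  # model-free reductions
  expect_equal(methyl_spectral_density(omega600, tau, 10e-12, 1),
               spectral_density(omega600, tau))
  expect_equal(methyl_spectral_density(omega600, tau, 0, 0.25),
               0.25 * spectral_density(omega600, tau))
  # arithmetic check at omega = 0: S2*tauc + (1-S2)*taue
  taue <- 1 / (1 / 22e-9 + 1 / 10e-12)
  expect_equal(methyl_spectral_density(0, 22e-9, 10e-12, 0.25),
               0.25 * 22e-9 + 0.75 * taue, tolerance = 1e-12)
  expect_error(methyl_spectral_density(0, 1e-9, 2e-9), "tau_internal")
})

test_that("cross-relaxation sign structure: zero crossing at omega*tau = sqrt(5)/2", {
  tau_star <- sqrt(5) / 2 / omega600
  s <- cross_relaxation_rate(2.5, tau_star, omega600)
  expect_equal(6 * spectral_density(2 * omega600, tau_star),
               spectral_density(0, tau_star), tolerance = 1e-9)
  expect_lt(abs(s) / abs(cross_relaxation_rate(2.5, 22e-9, omega600)), 1e-6)
  # slow tumbling (protein, 22 ns): spin-diffusion limit, negative NOE
  expect_lt(cross_relaxation_rate(2.5, 22e-9, omega600), 0)
  # free trisaccharide at 0.4 ns: past the null, weakly negative
  s04 <- cross_relaxation_rate(2.5, 0.4e-9, omega600)
  expect_lt(s04, 0)
  expect_lt(abs(s04), abs(cross_relaxation_rate(2.5, 22e-9, omega600)) / 20)
  # fast tumbling (0.1 ns): positive NOE
  expect_gt(cross_relaxation_rate(2.5, 0.1e-9, omega600), 0)
  expect_error(cross_relaxation_rate(0.3, 1e-9, omega600), "unphysical")
})

test_that("relaxation matrix entries match scalar recomputation", {
  conds <- corcema_conditions()
  # two protons at 2.5 A
  sys2 <- spin_system(c("L1", "P1"), c("ligand", "protein"),
                      rbind(c(0, 0, 0), c(2.5, 0, 0)),
                      saturated = c(FALSE, TRUE))
  R <- build_relaxation_matrix(sys2, "bound", conds)
  expect_true(isSymmetric(R))
  expect_equal(R["L1", "P1"],
               cross_relaxation_rate(2.5, conds$tau_c_bound, conds$larmor))
  expect_equal(R["L1", "L1"],
               auto_relaxation_rate(2.5, conds$tau_c_bound, conds$larmor))
  # r^-6 law: doubling all distances scales every rate by 2^-6
  sys2b <- spin_system(c("L1", "P1"), c("ligand", "protein"),
                       rbind(c(0, 0, 0), c(5, 0, 0)),
                       saturated = c(FALSE, TRUE))
  expect_equal(build_relaxation_matrix(sys2b, "bound", conds), R / 64,
               tolerance = 1e-12)
  # 3-spin linear chain vs hand-computed entries
  sys3 <- spin_system(c("L1", "L2", "P1"), c("ligand", "ligand", "protein"),
                      rbind(c(0, 0, 0), c(2, 0, 0), c(5, 0, 0)),
                      saturated = c(FALSE, FALSE, TRUE))
  R3 <- build_relaxation_matrix(sys3, "bound", conds)
  sg <- function(r) cross_relaxation_rate(r, conds$tau_c_bound, conds$larmor)
  rh <- function(r) auto_relaxation_rate(r, conds$tau_c_bound, conds$larmor)
  expect_equal(R3["L1", "L2"], sg(2))
  expect_equal(R3["L1", "P1"], sg(5))
  expect_equal(R3["L2", "P1"], sg(3))
  expect_equal(diag(R3), c(L1 = rh(2) + rh(5), L2 = rh(2) + rh(3),
                           P1 = rh(5) + rh(3)), tolerance = 1e-12)
})

test_that("distance cutoff prunes far protein protons; empty shell errors", {
  conds <- corcema_conditions(distance_cutoff_A = 8)
  sys <- spin_system(c("L1", "P1", "P2"),
                     c("ligand", "protein", "protein"),
                     rbind(c(0, 0, 0), c(3, 0, 0), c(30, 0, 0)),
                     saturated = c(FALSE, TRUE, TRUE))
  R <- build_relaxation_matrix(sys, "bound", conds)
  expect_equal(colnames(R), c("L1", "P1"))
  sysfar <- spin_system(c("L1", "P1"), c("ligand", "protein"),
                        rbind(c(0, 0, 0), c(30, 0, 0)),
                        saturated = c(FALSE, TRUE))
  expect_error(build_relaxation_matrix(sysfar, "bound", conds),
               "no protein protons within")
})

test_that("relaxation eigenvalues have positive real part on random systems", {
  for (s in 1:10) {
    sys <- gen_toy_complex(3, 4, seed = s)
    R <- build_relaxation_matrix(sys, "bound", corcema_conditions())
    expect_true(all(Re(eigen(R, only.values = TRUE)$values) > 0))
  }
})

test_that("kinetic part of the dynamics conserves exchanging magnetization", {
  sys <- gen_toy_complex(2, 2, seed = 4)
  conds <- corcema_conditions()
  dyn <- corcema_dynamics(sys, conds)
  kin <- dyn$kinetics
  k1 <- conds$kon * (kin$p0 - kin$complex_conc)
  nL <- length(dyn$ligand_labels)
  ## subtract the relaxation diagonals: the remaining kinetic part of each
  ## free/bound column pair must sum to zero (flux out of free = flux into
  ## bound, and vice versa)
  Rf <- build_relaxation_matrix(sys, "free", conds)
  Rb <- build_relaxation_matrix(sys, "bound", conds)
  for (i in seq_len(nL)) {
    iF <- dyn$i_free[i]; iB <- dyn$i_bound[i]
    kin_free <- c(dyn$D[iF, iF] - Rf[i, i], dyn$D[iB, iF])
    kin_bound <- c(dyn$D[iF, iB],
                   dyn$D[iB, iB] - Rb[dyn$ligand_labels[i],
                                      dyn$ligand_labels[i]])
    expect_equal(kin_free, c(k1, -k1), tolerance = 1e-12)
    expect_equal(sum(kin_free), 0, tolerance = 1e-9 * k1)
    expect_equal(sum(kin_bound), 0, tolerance = 1e-9 * max(1, kin$koff))
  }
})

test_that("predict_std trivial limits: no saturation, no binding", {
  sys <- gen_toy_complex(2, 3, seed = 2)
  conds <- corcema_conditions()
  # empty saturated set -> no perturbation
  sys0 <- sys; sys0$saturated <- rep(FALSE, length(sys0$labels))
  res0 <- predict_std(sys0, conds, paper_sat_times)
  expect_true(all(res0$std == 0))
  # kd -> infinity: transfer vanishes, monotonically in kd
  ref <- max(abs(predict_std(sys, conds, paper_sat_times)$std))
  m <- vapply(c(1e3, 1e5, 1e8), function(kd) {
    max(abs(predict_std(sys, corcema_conditions(kd_uM = kd),
                        paper_sat_times)$std))
  }, numeric(1))
  expect_true(all(diff(m) < 0))
  expect_lt(m[3], 1e-4 * ref)
})

test_that("matrix-exponential propagation matches adaptive ODE integration", {
  sys <- gen_toy_complex(2, 2, seed = 10)
  conds <- corcema_conditions()
  dyn <- corcema_dynamics(sys, conds)
  res <- predict_std(sys, conds, paper_sat_times, method = "eigen")
  res_expm <- predict_std(sys, conds, paper_sat_times, method = "expm")
  expect_equal(res$std, res_expm$std, tolerance = 1e-8)
  wss <- solve(dyn$D, dyn$c)
  W_ode <- ode_rk45(dyn$D, dyn$c, rep(0, length(dyn$c)), paper_sat_times)
  std_ode <- -(W_ode[, dyn$i_free, drop = FALSE] +
                 W_ode[, dyn$i_bound, drop = FALSE]) / dyn$kinetics$l0
  expect_lt(max(abs(res$std - std_ode)), 1e-8)
})

test_that("STD build-up from predict_std is monotone, saturating, and fittable", {
  sys <- gen_toy_complex(2, 4, seed = 6)
  ts <- c(0.25, 0.5, 1, 2, 3, 4, 6, 8, 12)
  # a modest leak rate bounds the build-up time constant, as in real
  # samples; without it distant protons stay in their linear regime
  res <- predict_std(sys, corcema_conditions(rho_leak = 0.3), ts)
  for (j in seq_len(ncol(res$std))) {
    y <- res$std[, j]
    expect_true(all(diff(y) > -1e-12))
    expect_true(all(y >= -1e-12 & y <= 1))
    # growth rate decays: approaching an asymptote
    expect_lt(diff(y)[length(y) - 1] / max(diff(y) / diff(ts)) /
                diff(ts)[length(y) - 1], 0.8)
    # cross-module consistency: the mono-exponential fit is well-behaved
    f <- fit_buildup(buildup_curve(ts, pmin(1, pmax(0, y))))
    expect_gt(f$std_max, 0); expect_gt(f$k_sat, 0)
    expect_lt(f$residual_norm, 0.05 * max(y))
  }
})

test_that("relabeling symmetry: swapping owners of a mirror system preserves STD", {
  # square geometry, mirror-symmetric under x -> 3 - x
  xyz <- rbind(c(0, 0, 0), c(0, 2, 0), c(3, 0, 0), c(3, 2, 0))
  conds <- corcema_conditions(p0_uM = 50, l0_mM = 0.05,
                              tau_c_free_ns = 22)  # equal taus, p0 = l0
  sysA <- spin_system(c("a1", "a2", "b1", "b2"),
                      c("ligand", "ligand", "protein", "protein"), xyz,
                      saturated = c(FALSE, FALSE, TRUE, TRUE))
  sysB <- spin_system(c("b1", "b2", "a1", "a2"),
                      c("ligand", "ligand", "protein", "protein"),
                      xyz[c(3, 4, 1, 2), ],
                      saturated = c(FALSE, FALSE, TRUE, TRUE))
  rA <- predict_std(sysA, conds, paper_sat_times)
  rB <- predict_std(sysB, conds, paper_sat_times)
  expect_equal(unname(rA$std), unname(rB$std), tolerance = 1e-9)
})

test_that("NOE R-factor arithmetic", {
  expect_equal(noe_r_factor(c(0.1, 0.2), c(0.1, 0.2)), 0)
  expect_equal(noe_r_factor(c(0, 0), c(0.1, 0.2)), 1)
  expect_equal(noe_r_factor(c(0.12, 0.18), c(0.1, 0.2)),
               sqrt(0.0008 / 0.05), tolerance = 1e-12)
  expect_error(noe_r_factor(c(0.1), c(0)), "all zero")
  expect_error(noe_r_factor(c(0.1, 0.2), c(0.1)), "aligned")
})
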