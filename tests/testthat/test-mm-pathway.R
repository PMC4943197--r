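test_that("reversible MM rate law: hand value, equilibrium, linearity", {
  expect_equal(mm_rate(2, 0, Keq = 10, Kf = 1, Kr = 1, V = 1), 2 / 3)
  # zero net rate exactly at thermodynamic equilibrium
  expect_equal(mm_rate(2, 20, Keq = 10, Kf = 1, Kr = 1, V = 3), 0)
  # linear in enzyme activity at fixed concentrations
  expect_equal(
    mm_rate(2, 1, 10, 0.5, 0.5, V = 2),
    2 * mm_rate(2, 1, 10, 0.5, 0.5, V = 1)
  )
})

test_that("steady state matches the linear-regime closed form at large Km", {
  # Km >> concentrations: saturation terms cancel and the balance is linear,
  # I = (V1 S + V2 E/Keq2) / (V2 + V1/Keq1) with V1 = 1, V2 = 0.99 at P = 0.01
  params <- mm_params(Km = 1e8)
  ss <- mm_steady_state(params, P = 0.01)
  expect_equal(ss$I, 2.099 / 1.09, tolerance = 1e-6)
})

test_that("steady state balances the two fluxes to high precision", {
  params <- mm_params(Km = 1)
  ss <- mm_steady_state(params, P = c(0.01, 0.094, 0.3))
  for (i in seq_len(nrow(ss))) {
    f1 <- mm_rate(2, ss$I[i], 10, 1, 1, V = 100 * ss$P[i])
    f2 <- mm_rate(ss$I[i], 1, 10, 1, 1, V = 1 - ss$P[i])
    expect_lt(abs(f1 - f2), 1e-10 * abs(f1))
    expect_gt(ss$I[i], 1 / 10)
    expect_lt(ss$I[i], 2 * 10)
  }
  # near the optimum the intermediate pool reaches ~9.8 mM
  expect_equal(ss$I[2], 9.8, tolerance = 0.01)
})

test_that("flux imbalance is monotone in I, so the root is unique", {
  params <- mm_params(Km = 0.1)
  P <- 0.05
  I <- seq(0.11, 19.9, length.out = 200)
  imbalance <- mm_rate(2, I, 10, 0.1, 0.1, V = 100 * P) -
    mm_rate(I, 1, 10, 0.1, 0.1, V = 1 - P)
  expect_true(all(diff(imbalance) < 0))
})

test_that("dilution cost leaves I unchanged and divides the flux by 1 + I c", {
  c1 <- mm_dilution_cost(100)
  expect_equal(c1, 1 / 400)
  base <- mm_steady_state(mm_params(Km = 1), 0.08)
  cost <- mm_steady_state(mm_params(Km = 1, dilution_cost = c1), 0.08)
  expect_equal(cost$I, base$I)
  expect_equal(cost$flux, base$flux)
  expect_equal(cost$net_flux, base$flux / (1 + base$I * c1))
})

test_that("grid optimization reproduces the printed optima", {
  fit <- mm_optimize(mm_params(Km = 1))
  expect_equal(fit$P_opt, 0.094)
  expect_equal(fit$I_opt, 9.8, tolerance = 0.01)
  # the optimum beats both grid neighbours
  i <- which(fit$curve$P == fit$P_opt)
  expect_gte(fit$net_flux_opt, fit$curve$net_flux[i - 1])
  expect_gte(fit$net_flux_opt, fit$curve$net_flux[i + 1])
  # intermediate dilution (100x lighter, 4 mM protein) shifts the optimum down
  fitc <- mm_optimize(mm_params(Km = 1, dilution_cost = mm_dilution_cost(100)))
  expect_equal(fitc$P_opt, 0.088)
  expect_equal(fitc$I_opt, 9.5, tolerance = 0.01)
})

test_that("refined optimum stays within one grid step of the grid optimum", {
  fit <- mm_optimize(mm_params(Km = 1), refine = TRUE)
  expect_lt(abs(fit$P_fine - fit$P_opt), 5e-4)
})

test_that("perturbation costs match the printed 2-fold and 1% values", {
  fit <- mm_optimize(mm_params(Km = 1))
  pert <- mm_perturb(fit, c(0.5, 1, 2))
  expect_equal(pert$s_over_Popt[2], 0)
  expect_equal(pert$s_over_Popt[3], 0.59, tolerance = 0.01)
  expect_equal(pert$s_over_Popt[1], 0.53, tolerance = 0.01)
  # high dilution cost (10x lighter intermediate): a 1% change costs ~2e-4 P
  fit10 <- mm_optimize(mm_params(Km = 1, dilution_cost = mm_dilution_cost(10)),
    refine = TRUE)
  p1 <- mm_perturb(fit10, 1.01)
  expect_equal(p1$s_over_Popt, 2e-4, tolerance = 0.5)
})

test_that("2-fold costs stay near 0.5 P_opt across four decades of Km", {
  for (Km in c(0.01, 0.1, 1, 10, 100)) {
    fit <- mm_optimize(mm_params(Km = Km), refine = TRUE)
    pert <- mm_perturb(fit, c(0.5, 2))
    expect_true(all(pert$s_over_Popt >= 0.4 & pert$s_over_Popt <= 0.8))
    p1 <- mm_perturb(fit, 1.01)
    expect_gt(p1$s_over_Popt, 1e-4 / 3)
    expect_lt(p1$s_over_Popt, 3e-4)
  }
})

test_that("high-cost 1% perturbations span the printed band across Km", {
  c10 <- mm_dilution_cost(10)
  for (Km in c(0.001, 0.01, 0.1, 1, 10)) {
    fit <- mm_optimize(mm_params(Km = Km, dilution_cost = c10), refine = TRUE)
    p <- mm_perturb(fit, 1.01)
    expect_gte(p$s_over_Popt, 1.4e-4 * 0.95)
    expect_lte(p$s_over_Popt, 2.7e-4 * 1.05)
  }
})

test_that("focusing on the second step behaves like a proper optimum too", {
  # the slow second enzyme takes most of the proteome, so the grid must
  # extend close to 1
  fit <- mm_optimize(mm_params(Km = 1, focal = "second"),
    P_grid = seq(5e-4, 0.995, by = 5e-4))
  expect_gt(fit$P_opt, 0.5)
  pert <- mm_perturb(fit, c(0.5, 1.05))
  expect_true(all(pert$s >= 0))
  expect_gt(fit$net_flux_opt, 0)
})

test_that("tidy and glance expose the curve and the optimum", {
  fit <- mm_optimize(mm_params(Km = 1))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("P", "I", "flux", "net_flux"))
  gl <- glance(fit)
  expect_equal(gl$P_opt, fit$P_opt)
  expect_equal(gl$Km, 1)
})
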