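test_that("growth rate is the f-weighted harmonic-mean synthesis rate", {
  expect_equal(growth_rate(0.5, rep(4, 20), rep(0.05, 20)), 2)
  f <- rep(1 / 20, 20)
  A <- 1:20
  expect_equal(growth_rate(0.3, A, f), 0.3 / sum(1 / (20 * (1:20))))
  expect_equal(growth_rate(0.6, A, f), 2 * growth_rate(0.3, A, f))
  expect_error(growth_rate(0.5, c(rep(4, 19), 0), f), "positive")
})

test_that("steady state matches the symmetric closed form", {
  p <- growth_params()
  R <- sqrt(2) - 1
  a <- growth_allocation(R = R, E = rep((1 - R) / 20, 20))
  ss <- growth_steady_state(p, a)
  A_expect <- 10 * (1 - R) / (1 + R)
  g_expect <- 10 * R * (1 - R) / (1 + R)
  expect_equal(ss$g, g_expect, tolerance = 1e-8)
  expect_equal(ss$A, rep(A_expect, 20), tolerance = 1e-8)
})

test_that("steady-state solutions satisfy both model equations", {
  set.seed(3)
  draws <- sample_growth_params(5, seed = 3)
  for (i in 1:5) {
    p <- draws$params[[i]]
    w <- c(0.4, 0.05, rep(0.55 / 19, 19))
    a <- growth_allocation(R = w[1], E = w[-1])
    ss <- growth_steady_state(p, a)
    # amino-acid balance: g f_i = E_i r_i (1 - A_i / 10)
    lhs <- ss$g * p$f
    rhs <- a$E * p$r * (1 - ss$A / 10)
    expect_lt(max(abs(lhs - rhs) / rhs), 1e-10)
    # synthesis rate consistency
    expect_lt(abs(ss$g - growth_rate(a$R, ss$A, p$f)) / ss$g, 1e-10)
    expect_true(all(ss$A > 0 & ss$A < 10))
  }
})

test_that("starving a used amino acid is reported as infeasible", {
  expect_error(growth_allocation(0.5, c(0, rep(0.5 / 19, 19))))
  p <- growth_params()
  # effectively zero capacity: growth collapses toward zero, not negative A
  a <- growth_allocation(R = 0.5, E = c(1e-12, rep((0.5 - 1e-12) / 19, 19)))
  expect_lt(growth_steady_state(p, a)$g, 1e-9)
})

test_that("allocation optimizer recovers the symmetric closed form", {
  fit <- growth_optimize(growth_params())
  expect_equal(fit$alloc$R, sqrt(2) - 1, tolerance = 1e-6)
  expect_equal(fit$g_opt, 10 * (sqrt(2) - 1) * (2 - sqrt(2)) / sqrt(2),
    tolerance = 1e-6)
  # by symmetry the focal enzyme gets the same share as the others
  expect_equal(fit$P_opt, (1 - fit$alloc$R) / 20, tolerance = 1e-5)
  # local optimality probe
  for (fc in c(1 - 1e-3, 1 + 1e-3)) {
    expect_lte(grid_growth_curve(fit, fc), fit$g_opt + 1e-12)
  }
})

test_that("optimizer rejects asymmetric non-focal parameters", {
  f <- c(0.2, seq(0.01, 0.07, length.out = 19))
  f <- f / sum(f)
  expect_error(
    growth_optimize(growth_params(f = f, r = rep(5, 20))),
    "non-focal"
  )
})

test_that("perturbing the focal enzyme away from the optimum always costs", {
  draws <- sample_growth_params(4, seed = 9)
  for (i in 1:4) {
    fit <- growth_optimize(draws$params[[i]])
    pert <- growth_perturb(fit, c(0.25, 0.5, 0.9, 1, 1.1, 2, 4))
    expect_equal(pert$s[pert$factor == 1], 0, tolerance = 1e-9)
    expect_true(all(pert$s >= -1e-9))
    # doubling costs between half of P_opt and P_opt
    s2 <- pert$s_over_Popt[pert$factor == 2]
    expect_gte(s2, 0.5)
    expect_lte(s2, 1)
  }
})

test_that("small relative changes cost between 1x and ~3x the eps^2 bound", {
  draws <- sample_growth_params(4, seed = 21)
  eps <- c(-0.05, -0.02, 0.02, 0.05)
  ratios <- c()
  for (i in 1:4) {
    fit <- growth_optimize(draws$params[[i]])
    pert <- growth_perturb(fit, 1 + eps)
    ratio <- pert$s_over_Popt / eps^2
    # always above the quadratic lower bound, never an order of magnitude up
    expect_true(all(ratio >= 0.95 & ratio <= 5))
    # well below the linear cost |eps| * P_opt
    expect_true(all(pert$s_over_Popt < abs(eps)))
    ratios <- c(ratios, ratio)
  }
  # typically about three-fold above the lower bound
  expect_gt(stats::median(ratios), 1.5)
  expect_lt(stats::median(ratios), 4)
})

test_that("half-max expression sits about 3-fold below the optimum", {
  fit <- growth_optimize(growth_params())
  hm <- growth_half_max(fit)
  expect_lt(hm$K_half, fit$P_opt)
  # growth at K_half equals half the optimum
  g_half <- grid_growth_curve(fit, hm$K_half / fit$P_opt)
  expect_equal(g_half, fit$g_opt / 2, tolerance = 1e-8)
  # g increases monotonically from K_half up to the optimum
  fcs <- seq(hm$K_half / fit$P_opt, 1, length.out = 25)
  g <- grid_growth_curve(fit, fcs)
  expect_true(all(diff(g) > 0))
  # dense-grid oracle for K_half
  fcs_dense <- seq(0.05, 1, length.out = 2000)
  g_dense <- grid_growth_curve(fit, fcs_dense)
  oracle <- fcs_dense[which.min(abs(g_dense - fit$g_opt / 2))] * fit$P_opt
  expect_equal(hm$K_half, oracle, tolerance = 1e-3)
  expect_gt(hm$ratio, 2)
  expect_lt(hm$ratio, 5)
})

test_that("rescaling all enzyme rates rescales growth without reordering", {
  draws <- sample_growth_params(1, seed = 5)
  p <- draws$params[[1]]
  fit <- growth_optimize(p)
  p2 <- growth_params(f = p$f, r = 2 * p$r)
  fit2 <- growth_optimize(p2)
  expect_gt(fit2$g_opt, fit$g_opt)
  # faster enzymes need less proteome: enzyme shares shrink, ribosome grows
  expect_lt(fit2$P_opt, fit$P_opt)
  expect_gt(fit2$alloc$R, fit$alloc$R)
})

test_that("tidy and glance summarise a growth fit", {
  fit <- growth_optimize(growth_params())
  td <- tidy(fit)
  expect_equal(nrow(td), 20)
  expect_equal(sum(td$E) + fit$alloc$R, 1, tolerance = 1e-9)
  gl <- glance(fit)
  expect_named(gl, c("f1", "r1", "R_opt", "E1_opt", "g_opt", "convergence"))
  expect_equal(gl$convergence, 0)
})
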