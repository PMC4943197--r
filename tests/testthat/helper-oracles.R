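# brute-force oracles used to cross-check closed forms and solvers

# grid maximizer of the cost-benefit net benefit
grid_cb_optimum <- function(f, K, n_grid = 1e6) {
  P <- seq(0, min(0.999, 20 * sqrt(K * f)), length.out = n_grid)
  b <- f * P / (K + P) - P
  i <- which.max(b)
  list(P_opt = P[i], s_opt = b[i], step = P[2] - P[1])
}

# random net-beneficial (f, K) pairs on log scales
random_fk <- function(n, f_over_K_min = 1.5) {
  f <- 10^stats::runif(n, -5, 0)
  K <- 10^stats::runif(n, log10(2e-7), -1)
  keep <- K < f / f_over_K_min
  list(f = f[keep], K = K[keep])
}

# dense-grid growth rate of the symmetric growth model as a function of
# the focal enzyme's fraction, optimum rescaling as in growth_perturb()
grid_growth_curve <- function(fit, factors) {
  vapply(factors, function(fc) {
    E1 <- fc * fit$P_opt
    scale <- (1 - E1) / (1 - fit$P_opt)
    alloc <- growth_allocation(
      R = fit$alloc$R * scale,
      E = c(E1, fit$alloc$E[-1] * scale)
    )
    growth_steady_state(fit$params, alloc)$g
  }, numeric(1))
}
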