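#' Parameters of the amino-acid-assembly growth model
#'
#' A coarse-grained cell with 20 amino acids, one synthesis enzyme per
#' amino acid, and a "ribosome" that assembles amino acids into protein.
#' Growth rate equals the protein synthesis rate
#' \deqn{g = \frac{R}{\sum_i f_i / A_i}}
#' (ribosome concentration times the `f`-weighted harmonic mean of the
#' amino-acid concentrations), and each enzyme follows unsaturated
#' reversible kinetics, so that at steady state
#' \deqn{g f_i = E_i r_i (S_{aa} - A_i / K_{eq})}
#' with precursor concentration `S_aa = 1` and equilibrium constant
#' `Keq = 10`, putting each `A_i` in `(0, 10)`.
#'
#' The model is studied with one focal amino acid: `f[1]` and `r[1]` vary
#' while the 19 others share common values (see [sample_growth_params()]
#' for the random-parameter procedure).
#'
#' @param f Vector of 20 amino-acid usage fractions, positive, summing
#'   to 1.
#' @param r Vector of 20 enzyme rate constants relative to the ribosome's
#'   rate, positive; rescaled draws average 5, making enzymes typically
#'   faster (lighter) than the ribosome.
#' @param S_aa Precursor substrate concentration (arbitrary units).
#' @param Keq Equilibrium constant of amino-acid synthesis.
#' @return An object of class `growth_params`.
#' @examples
#' growth_params() # the symmetric instance: all f = 0.05, all r = 5
#' @export
growth_params <- function(f = rep(1 / 20, 20), r = rep(5, 20),
                          S_aa = 1, Keq = 10) {
  stopifnot(
    length(f) == length(r),
    all(f > 0), all(r > 0), S_aa > 0, Keq > 0
  )
  if (abs(sum(f) - 1) > 1e-12) {
    rlang::abort("`f` must sum to 1 (amino-acid usage fractions).")
  }
  structure(
    list(f = f, r = r, S_aa = S_aa, Keq = Keq, n = length(f)),
    class = "growth_params"
  )
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf(
    "Growth model: %d amino acids, f1 = %.4g, r1 = %.4g, mean(r) = %.4g\n",
    x$n, x$f[1], x$r[1], mean(x$r)
  ))
  invisible(x)
}

#' Proteome allocation for the growth model
#'
#' Partition of the fixed total proteome between the ribosome (`R`) and
#' the synthesis enzymes (`E`, one fraction per amino acid), summing to 1.
#'
#' @param R Ribosome proteome fraction, in `(0, 1)`.
#' @param E Vector of enzyme proteome fractions, positive.
#' @return An object of class `growth_allocation`.
#' @export
growth_allocation <- function(R, E) {
  stopifnot(R > 0, all(E > 0))
  if (abs(R + sum(E) - 1) > 1e-9) {
    rlang::abort("`R + sum(E)` must equal 1 (the whole proteome).")
  }
  structure(list(R = R, E = E), class = "growth_allocation")
}

#' Growth rate given amino-acid concentrations
#'
#' The protein synthesis rate `g = R / sum(f_i / A_i)`: amino-acid
#' incorporation is first-order, so translation time is a weighted sum of
#' inverse concentrations, and synthesis rate is the ribosome
#' concentration times the `f`-weighted harmonic mean of `A`.
#'
#' @param R Ribosome proteome fraction.
#' @param A Vector of amino-acid concentrations, all positive.
#' @param f Vector of usage fractions, same length as `A`, summing to 1.
#' @return The growth rate `g` (per unit ribosome turnover).
#' @examples
#' growth_rate(0.5, rep(4, 20), rep(0.05, 20)) # 2
#' @export
growth_rate <- function(R, A, f) {
  if (any(A <= 0)) rlang::abort("all amino-acid concentrations must be positive.")
  stopifnot(length(A) == length(f))
  R / sum(f / A)
}

# amino-acid concentrations implied by growth rate g (balance equations)
growth_A_of_g <- function(g, params, alloc) {
  params$Keq * (params$S_aa - g * params$f / (alloc$E * params$r))
}

#' Steady state of the growth model
#'
#' Solves the coupled balance equations `g f_i = E_i r_i (S_aa - A_i/Keq)`
#' together with `g = R / sum(f_i / A_i)`. Substituting the balance
#' solution `A_i(g) = Keq (S_aa - g f_i / (E_i r_i))` reduces the system
#' to a single scalar equation in `g` whose left side is strictly
#' decreasing, so the root is unique on `(0, g_max)` with
#' `g_max = min_i E_i r_i S_aa / f_i` (the rate at which the slowest
#' enzyme can no longer keep its amino acid above zero). The root is
#' bracketed and solved to near machine precision.
#'
#' @param params A [growth_params()] object.
#' @param alloc A [growth_allocation()] object (lengths must match).
#' @return A list with elements `g` (growth rate) and `A` (vector of
#'   steady-state amino-acid concentrations, each in `(0, Keq * S_aa)`).
#' @examples
#' p <- growth_params()
#' a <- growth_allocation(R = sqrt(2) - 1, E = rep((2 - sqrt(2)) / 20, 20))
#' growth_steady_state(p, a)$g # ~1.7157
#' @export
growth_steady_state <- function(params, alloc) {
  stopifnot(inherits(params, "growth_params"), inherits(alloc, "growth_allocation"))
  if (length(alloc$E) != params$n) {
    rlang::abort("allocation and parameters must have the same number of enzymes.")
  }
  g_max <- min(alloc$E * params$r * params$S_aa / params$f)
  if (g_max <= 0) {
    rlang::abort("infeasible allocation: an enzyme with zero capacity must supply a used amino acid.")
  }
  h <- function(g) {
    A <- growth_A_of_g(g, params, alloc)
    alloc$R / sum(params$f / A) - g
  }
  root <- stats::uniroot(
    h,
    lower = g_max * 1e-14, upper = g_max * (1 - 1e-13),
    tol = .Machine$double.eps, maxiter = 1000L
  )
  g <- root$root
  # one fixed-point polish: A(g) is exact for the balance equations, so
  # re-evaluating the synthesis rate at A(g) removes the residual in g
  g <- alloc$R / sum(params$f / growth_A_of_g(g, params, alloc))
  list(g = g, A = growth_A_of_g(g, params, alloc))
}

# allocation from softmax weights over (ribosome, focal enzyme, rest)
growth_alloc_from_theta <- function(theta, n) {
  w <- exp(c(theta, 0) - max(theta, 0))
  w <- w / sum(w)
  growth_allocation(R = w[1], E = c(w[2], rep(w[3] / (n - 1), n - 1)))
}

#' Optimal proteome allocation in the growth model
#'
#' Maximizes the steady-state growth rate over the ribosome fraction `R`
#' and the focal enzyme's fraction `E[1]`, with the 19 non-focal enzymes
#' constrained to equal shares of the remainder (the parameters of amino
#' acids 2..20 are identical, so the optimum is symmetric in them). The
#' search runs over an unconstrained softmax parameterization of the
#' three-way split (ribosome, focal enzyme, rest), which keeps every
#' candidate allocation strictly feasible, using Nelder-Mead from four
#' starting points with a relative tolerance of 1e-14 on `g`.
#'
#' @param params A [growth_params()] object whose non-focal `f` and `r`
#'   entries are equal.
#' @return An object of class `growth_fit` with elements `params`,
#'   `alloc` (the optimal [growth_allocation()]), `g_opt`, `A_opt`,
#'   `P_opt` (the focal enzyme's optimal fraction `E[1]`), and
#'   `convergence` (0 for success). Supports [generics::tidy()],
#'   [generics::glance()].
#' @examples
#' fit <- growth_optimize(growth_params())
#' glance(fit) # R_opt = sqrt(2) - 1, g_opt ~ 1.7157
#' @export
growth_optimize <- function(params) {
  stopifnot(inherits(params, "growth_params"))
  if (params$n > 2) {
    spread <- function(x) diff(range(x[-1])) > 1e-9 * max(abs(x[-1]))
    if (spread(params$f) || spread(params$r)) {
      rlang::abort("non-focal `f` and `r` must be equal for the symmetric optimization.")
    }
  }
  objective <- function(theta) {
    alloc <- growth_alloc_from_theta(theta, params$n)
    -growth_steady_state(params, alloc)$g
  }
  starts <- list(c(0, 0), c(1, -1), c(-1, 1), c(-2, -2))
  best <- NULL
  for (st in starts) {
    o <- stats::optim(st, objective,
      method = "Nelder-Mead",
      control = list(reltol = 1e-14, maxit = 5000L)
    )
    if (is.null(best) || o$value < best$value) best <- o
  }
  # polish from the winning start (restarting Nelder-Mead rebuilds the
  # simplex at a smaller scale around the candidate optimum)
  best <- stats::optim(best$par, objective,
    method = "Nelder-Mead",
    control = list(reltol = 1e-15, maxit = 5000L)
  )
  alloc <- growth_alloc_from_theta(best$par, params$n)
  ss <- growth_steady_state(params, alloc)
  structure(
    list(
      params = params, alloc = alloc,
      g_opt = ss$g, A_opt = ss$A, P_opt = alloc$E[1],
      convergence = best$convergence
    ),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "Growth-model optimum: R = %.4f, focal E1 = %.4g, g = %.6f\n",
    x$alloc$R, x$P_opt, x$g_opt
  ))
  invisible(x)
}

#' @describeIn growth_optimize Per-amino-acid table: `amino_acid`, `f`,
#'   `r`, `E` (optimal fraction), `A` (steady-state concentration).
#' @param x A `growth_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.growth_fit <- function(x, ...) {
  tibble::tibble(
    amino_acid = seq_len(x$params$n),
    f = x$params$f, r = x$params$r,
    E = x$alloc$E, A = x$A_opt
  )
}

#' @describeIn growth_optimize One-row summary: `f1`, `r1`, `R_opt`,
#'   `E1_opt`, `g_opt`, `convergence`.
#' @exportS3Method generics::glance
glance.growth_fit <- function(x, ...) {
  tibble::tibble(
    f1 = x$params$f[1], r1 = x$params$r[1],
    R_opt = x$alloc$R, E1_opt = x$P_opt,
    g_opt = x$g_opt, convergence = x$convergence
  )
}

# allocation after scaling the focal enzyme by `factor`, all other
# proteins (ribosome included) rescaled by a common factor so the
# proteome still sums to 1
growth_perturbed_alloc <- function(fit, factor) {
  E1 <- factor * fit$P_opt
  if (E1 >= 1) rlang::abort("`factor * P_opt` must stay below 1.")
  scale <- (1 - E1) / (1 - fit$P_opt)
  growth_allocation(
    R = fit$alloc$R * scale,
    E = c(E1, fit$alloc$E[-1] * scale)
  )
}

#' Selection against perturbing the focal enzyme in the growth model
#'
#' Changes the focal enzyme's proteome fraction from its optimum to
#' `factor * P_opt`, rescales the ribosome and all other enzymes by a
#' common factor so total protein stays at 1, re-solves the steady state,
#' and reports `s = 1 - g / g_opt` (non-negative at a true optimum).
#'
#' @param fit A `growth_fit` from [growth_optimize()].
#' @param factor Multiplicative change(s) in expression, `> 0`. Vectorized.
#' @return A tibble with columns `factor`, `epsilon`, `P`, `s`,
#'   `s_over_Popt`.
#' @examples
#' fit <- growth_optimize(growth_params())
#' growth_perturb(fit, c(0.5, 2))
#' @export
growth_perturb <- function(fit, factor) {
  stopifnot(inherits(fit, "growth_fit"), all(factor > 0))
  s <- vapply(factor, function(fc) {
    alloc <- growth_perturbed_alloc(fit, fc)
    1 - growth_steady_state(fit$params, alloc)$g / fit$g_opt
  }, numeric(1))
  tibble::tibble(
    factor = factor, epsilon = factor - 1, P = factor * fit$P_opt,
    s = s, s_over_Popt = s / fit$P_opt
  )
}

#' Half-max expression level of the focal enzyme
#'
#' The expression level `K_half` below the optimum at which the growth
#' rate falls to half its maximum, by analogy with the half-max parameter
#' `K` of the cost-benefit form. `g` is increasing in the focal fraction
#' on the downward branch and tends to 0 as the fraction does, so the
#' root is found by bracketed search on the change factor in `(0, 1)`.
#'
#' @param fit A `growth_fit` from [growth_optimize()].
#' @return A tibble with columns `K_half`, `P_opt`, `ratio`
#'   (`P_opt / K_half`; about 3 across random parameter settings).
#' @export
growth_half_max <- function(fit) {
  stopifnot(inherits(fit, "growth_fit"))
  target <- function(fc) {
    alloc <- growth_perturbed_alloc(fit, fc)
    growth_steady_state(fit$params, alloc)$g - fit$g_opt / 2
  }
  root <- stats::uniroot(target, lower = 1e-9, upper = 1, tol = 1e-12)
  K_half <- root$root * fit$P_opt
  tibble::tibble(K_half = K_half, P_opt = fit$P_opt, ratio = fit$P_opt / K_half)
}
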