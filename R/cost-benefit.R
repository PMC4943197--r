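#' Net benefit of expressing a protein under the cost-benefit form
#'
#' Fitness contribution of a protein expressed at proteome fraction `P`,
#' modelled as a saturating benefit minus a linear cost:
#' \deqn{b(P) = f \frac{P}{K + P} - P}
#' where `f` is the maximum possible benefit and `K` the expression fraction
#' at which the benefit reaches half its maximum. Both `P` and `K` are
#' dimensionless fractions of total cellular protein; `f` is a dimensionless
#' fitness fraction. The form arises as the small-`P` limit of the
#' steady-state flux through a linear pathway of unsaturated reversible
#' enzymes when all non-focal proteins co-vary to keep total protein fixed.
#'
#' @param P Expression level, fraction of total cellular protein in `[0, 1)`.
#'   Vectorized.
#' @param f Maximum benefit, in `(0, 1]`.
#' @param K Half-max expression fraction, in `(0, 1)`.
#' @return Numeric vector of net fitness benefits (dimensionless).
#' @seealso [cb_optimum()] for the optimal expression level,
#'   [selection_exact()] for the cost of deviating from it.
#' @examples
#' net_benefit(0.09, f = 1, K = 0.01) # 0.81
#' @export
net_benefit <- function(P, f, K) {
  check_fraction(P, "P", allow_zero = TRUE)
  stopifnot(f > 0, f <= 1, K > 0, K < 1)
  f * P / (K + P) - P
}

#' Optimal expression level under the cost-benefit form
#'
#' Closed-form maximizer of [net_benefit()]:
#' \deqn{P_{opt} = \sqrt{K f} - K, \qquad s_{opt} = (\sqrt f - \sqrt K)^2}
#' `s_opt` is the net benefit at the optimum, i.e. the full selection
#' coefficient for losing the gene. Requires `K < f`, otherwise no
#' expression level is net-beneficial.
#'
#' @inheritParams net_benefit
#' @return A tibble with columns `f`, `K`, `P_opt`, `s_opt` (one row per
#'   parameter pair; `f` and `K` are recycled to a common length).
#' @examples
#' cb_optimum(f = 1, K = 0.01) # P_opt = 0.09, s_opt = 0.81
#' @export
cb_optimum <- function(f, K) {
  n <- vctrs_recycle_common(f = f, K = K)
  f <- n$f; K <- n$K
  stopifnot(all(f > 0), all(f <= 1), all(K > 0), all(K < 1))
  if (any(K >= f)) {
    rlang::abort("`K` must be smaller than `f`: no expression level is net-beneficial otherwise.")
  }
  tibble::tibble(
    f = f, K = K,
    P_opt = sqrt(K * f) - K,
    s_opt = (sqrt(f) - sqrt(K))^2
  )
}

#' Relative flux through a linear pathway ("metabolic" form)
#'
#' The exact steady-state flux of a linear pathway of unsaturated reversible
#' enzymes as a function of the focal enzyme's proteome fraction `P`, with
#' all other enzymes scaled by `1 - P` to keep total protein fixed:
#' \deqn{F(P) \propto \frac{P}{K + P/(1-P)}}
#' This is the parent of the cost-benefit form: for `K << 1` and `P << 1`
#' the two agree closely (see [compare_forms()]).
#'
#' @inheritParams net_benefit
#' @param K Ratio of the cost (mass per unit activity) of the focal enzyme
#'   to the pooled cost of the rest of the pathway; positive, dimensionless.
#' @return Numeric vector of relative fluxes, normalised so the flux at the
#'   optimum equals `s_opt` of [metabolic_optimum()].
#' @export
metabolic_flux <- function(P, K) {
  check_fraction(P, "P", allow_zero = TRUE)
  stopifnot(K > 0)
  P / (K + P / (1 - P))
}

#' Optimal expression level under the metabolic form
#'
#' Closed-form maximizer of [metabolic_flux()]:
#' \deqn{P_{opt} = \frac{\sqrt K}{1 + \sqrt K}, \qquad
#'       s_{opt} = \frac{1}{(1 + \sqrt K)^2}}
#'
#' @param K Cost ratio as in [metabolic_flux()]. Vectorized.
#' @return A tibble with columns `K`, `P_opt`, `s_opt`.
#' @examples
#' metabolic_optimum(0.01) # P_opt ~ 0.0909: an essential gene with
#' # K = 0.01 is optimally ~9% of cellular protein
#' @export
metabolic_optimum <- function(K) {
  stopifnot(all(K > 0))
  rk <- sqrt(K)
  tibble::tibble(K = K, P_opt = rk / (1 + rk), s_opt = 1 / (1 + rk)^2)
}

#' Compare the metabolic and cost-benefit optima
#'
#' Fractional differences between the optima of the exact linear-pathway
#' flux and its cost-benefit approximation with `f = 1`, relative to the
#' metabolic (exact) values. Both differences are available in closed form:
#' the difference in `P_opt` is exactly `K` and the difference in `s_opt`
#' is `2K - K^2`, so both vanish as `K -> 0` and grow monotonically in `K`.
#'
#' @param K Cost ratio, in `[0, 1)`. Vectorized; `K = 0` returns zeros.
#' @return A tibble with columns `K`, `dP_opt`, `ds_opt` (fractional
#'   differences, dimensionless, non-negative).
#' @examples
#' compare_forms(0.01) # both differences in the 1-2% range
#' @export
compare_forms <- function(K) {
  stopifnot(all(K >= 0), all(K < 1))
  out <- tibble::tibble(K = K, dP_opt = NA_real_, ds_opt = NA_real_)
  zero <- K == 0
  out$dP_opt[zero] <- 0; out$ds_opt[zero] <- 0
  if (any(!zero)) {
    Kp <- K[!zero]
    met <- metabolic_optimum(Kp)
    cb <- cb_optimum(f = 1, K = Kp)
    out$dP_opt[!zero] <- (met$P_opt - cb$P_opt) / met$P_opt
    out$ds_opt[!zero] <- (met$s_opt - cb$s_opt) / met$s_opt
  }
  out
}

#' Exact selection coefficient for nonoptimal expression
#'
#' Fitness reduction when a protein's expression is moved from its optimum
#' `P_opt` to `factor * P_opt`, under the cost-benefit form:
#' \deqn{s = b(P_{opt}) - b(x \cdot P_{opt})}
#' with `b` the net benefit. `s >= 0` for every `factor` because `P_opt`
#' maximizes `b`; `factor = 0` corresponds to gene loss (`s = s_opt`),
#' `factor = 0.5` to halved expression, `factor = 2` to a duplication.
#'
#' @inheritParams net_benefit
#' @param factor Multiplicative change `x = P / P_opt`, `>= 0`. Vectorized;
#'   `f`, `K` and `factor` are recycled to a common length.
#' @return A tibble with columns `f`, `K`, `P_opt`, `factor`, `epsilon`
#'   (`factor - 1`), and `s` (selection coefficient, `>= 0`, where positive
#'   values denote a fitness reduction).
#' @examples
#' selection_exact(f = 1, K = 1e-6, factor = 0.5) # s close to 0.5 * P_opt
#' @export
selection_exact <- function(f, K, factor) {
  n <- vctrs_recycle_common(f = f, K = K, factor = factor)
  f <- n$f; K <- n$K; factor <- n$factor
  stopifnot(all(factor >= 0))
  opt <- cb_optimum(f, K)
  P_new <- factor * opt$P_opt
  if (any(P_new >= 1)) {
    rlang::abort("`factor * P_opt` must stay below 1 (the whole proteome).")
  }
  tibble::tibble(
    f = f, K = K, P_opt = opt$P_opt,
    factor = factor, epsilon = factor - 1,
    s = net_benefit(opt$P_opt, f, K) - net_benefit(P_new, f, K)
  )
}

#' Small-change (quadratic) approximation to the selection coefficient
#'
#' For a relative change `epsilon` in expression away from the optimum,
#' the cost-benefit form gives, to leading order,
#' \deqn{s \approx \frac{\epsilon^2 P_{opt}}{1 + \epsilon}}
#' returned as a magnitude (`s >= 0`). The approximation is accurate to
#' within 2-fold whenever `f > 10 K`; e.g. a 1% change costs about
#' `1e-4 * P_opt` and a 2-fold change about `0.5 * P_opt`.
#'
#' @param epsilon Relative change in expression, `> -1`. Vectorized.
#' @param P_opt Optimal expression level(s), fraction of total protein.
#' @return Numeric vector of approximate selection coefficients.
#' @examples
#' selection_quadratic(0.01, P_opt = 1e-3) # ~1e-7
#' @export
selection_quadratic <- function(epsilon, P_opt = 1) {
  if (any(epsilon <= -1)) {
    rlang::abort("`epsilon` must exceed -1 (expression cannot go below zero).")
  }
  epsilon^2 * P_opt / (1 + epsilon)
}

#' Reference cost curves: linear cost and rate-limiting step
#'
#' Two comparison models for the cost of a change `epsilon` in expression
#' at level `P`: the linear relationship `|s| = |epsilon| * P` (the cost of
#' excess protein with no incremental benefit, appropriate for tightly
#' bound heteromeric complexes) and the rate-limiting-step relationship
#' `|s| = |epsilon|` (flux directly proportional to the focal enzyme).
#' These involve no optimization; they bracket the package's model curves
#' from above.
#'
#' @param epsilon Relative change in expression. Vectorized.
#' @param P Expression level, fraction of total protein, `> 0`.
#' @return A tibble with columns `epsilon`, `P`, `linear`, `rate_limiting`.
#' @export
reference_costs <- function(epsilon, P) {
  n <- vctrs_recycle_common(epsilon = epsilon, P = P)
  stopifnot(all(n$P > 0))
  tibble::tibble(
    epsilon = n$epsilon, P = n$P,
    linear = abs(n$epsilon) * n$P,
    rate_limiting = abs(n$epsilon)
  )
}
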