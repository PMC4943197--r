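#' Log-linear flux approximation from metabolic control analysis
#'
#' Metabolic control analysis approximates the log flux as linear in the
#' log enzyme levels, `F ∝ prod_i P_i^{C_i}` with control coefficients
#' `C_i`. Varying one protein at level `P` while the others co-vary
#' proportionally to keep total protein at 1 gives
#' \deqn{F \propto P^{C} (1 - P)^{C_{tot} - C}}
#' where `C_tot` is the sum of all control coefficients. For a purely
#' metabolic system the summation theorem fixes `C_tot = 1`, and the flux
#' is then maximized at `P = C`.
#'
#' @param P Focal protein's proteome fraction(s), in `(0, 1)`. Vectorized.
#' @param C Control coefficient of the focal protein, `0 < C <= C_tot`.
#' @param C_tot Sum of all control coefficients, `>= C`.
#' @return Numeric vector of relative fluxes (arbitrary normalization).
#' @examples
#' P <- seq(0.001, 0.1, by = 0.001)
#' P[which.max(mca_flux(P, C = 0.01))] # 0.01
#' @export
mca_flux <- function(P, C, C_tot = 1) {
  check_fraction(P, "P")
  stopifnot(C > 0, C_tot >= C)
  P^C * (1 - P)^(C_tot - C)
}

#' Fitness cost of expressing useless protein
#'
#' If a fraction `f_U` of the proteome is replaced by protein with no
#' catalytic role, every functional protein is diluted by `1 - f_U` and
#' the log-linear flux gives a growth rate of
#' `g(f_U) = g(0) * (1 - f_U)^{C_tot}`, hence a cost
#' \deqn{s = 1 - (1 - f_U)^{C_{tot}}}
#' which equals `f_U` exactly when `C_tot = 1`: the cost of useless
#' protein is the fraction of protein it accounts for.
#'
#' @param f_U Useless-protein fraction(s), in `[0, 1)`. Vectorized.
#' @param C_tot Sum of control coefficients, `>= 1` (a cost of useless
#'   protein at least equal to its level forces `C_tot >= 1`).
#' @return Numeric vector of selection coefficients.
#' @examples
#' useless_protein_cost(0.05) # 0.05
#' @export
useless_protein_cost <- function(f_U, C_tot = 1) {
  check_fraction(f_U, "f_U", allow_zero = TRUE)
  stopifnot(C_tot >= 1)
  1 - (1 - f_U)^C_tot
}

#' MCA selection coefficient for a change in expression
#'
#' Under the log-linear flux with `C_tot = 1` and a small optimal level
#' `P_opt`, moving expression from the optimum by a relative change
#' `epsilon` costs
#' \deqn{s \approx |{-\epsilon} + \ln(1 + \epsilon)| \cdot P_{opt}}
#' i.e. about `0.5 epsilon^2 P_opt` for small changes — roughly half the
#' cost-benefit coefficient. Doubling expression (`epsilon = 1`) costs
#' about `0.31 P_opt`, halving (`epsilon = -0.5`) about `0.19 P_opt`, and
#' a 1% change about `5e-5 P_opt`. For `C_tot > 1` the cost of
#' above-optimal expression scales in proportion to `C_tot`; the scaling
#' of below-optimal deviations is not specified by the approximation, so
#' downward changes always use the `C_tot = 1` expression.
#'
#' @param epsilon Relative change(s) in expression, `> -1`. Vectorized.
#' @param P_opt Optimal expression level(s), fraction of total protein.
#' @param C_tot Sum of control coefficients, `>= 1`; scales the cost of
#'   upward deviations only.
#' @return Numeric vector of selection coefficients (magnitudes).
#' @examples
#' mca_selection(1) / 1 # ~0.31
#' mca_selection(-0.5) # ~0.19
#' @export
mca_selection <- function(epsilon, P_opt = 1, C_tot = 1) {
  if (any(epsilon <= -1)) {
    rlang::abort("`epsilon` must exceed -1 (expression cannot go below zero).")
  }
  stopifnot(C_tot >= 1)
  base <- abs(-epsilon + log1p(epsilon)) * P_opt
  ifelse(epsilon > 0, base * C_tot, base)
}
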