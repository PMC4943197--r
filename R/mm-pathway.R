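#' Parameters for the two-step reversible Michaelis-Menten pathway
#'
#' The pathway converts a substrate S to an end product E through one
#' intermediate I (S <-> I <-> E), with both reactions mildly favorable.
#' The focal enzyme catalyses the first step and receives proteome fraction
#' `P`; the second enzyme receives the remainder, so its activity is
#' `V2 = 1 - P`. To keep the focal enzyme's optimal expression moderate, it
#' is `activity_ratio` times more active per unit mass, `V1 = 100 * P` by
#' default. All four Michaelis constants share the value `Km`.
#'
#' High intermediate concentrations can be penalised through
#' `dilution_cost` (`c`, per mM): the flux is divided by `1 + I * c`,
#' modelling the dilution of both enzymes by accumulated intermediate.
#' See [mm_dilution_cost()] for deriving `c` from a molecular-weight ratio.
#'
#' @param S Substrate concentration, mM.
#' @param E_end End-product concentration, mM.
#' @param Keq1,Keq2 Equilibrium constants of the two steps, dimensionless.
#' @param Km Shared Michaelis constant for every saturation term, mM.
#' @param activity_ratio Activity per unit mass of enzyme 1 relative to
#'   enzyme 2, dimensionless.
#' @param dilution_cost Intermediate-dilution coefficient `c`, per mM;
#'   `0` disables the cost.
#' @param focal Which step the focal enzyme catalyses. The second-step
#'   variant assigns `V2 = P` and `V1 = activity_ratio * (1 - P)`.
#' @return An object of class `mm_params` (a named list).
#' @examples
#' mm_params(Km = 1)
#' @export
mm_params <- function(S = 2, E_end = 1, Keq1 = 10, Keq2 = 10, Km = 1,
                      activity_ratio = 100, dilution_cost = 0,
                      focal = c("first", "second")) {
  focal <- match.arg(focal)
  stopifnot(
    S > 0, E_end > 0, Keq1 > 0, Keq2 > 0, Km > 0,
    activity_ratio > 0, dilution_cost >= 0
  )
  structure(
    list(
      S = S, E_end = E_end, Keq1 = Keq1, Keq2 = Keq2, Km = Km,
      activity_ratio = activity_ratio, dilution_cost = dilution_cost,
      focal = focal
    ),
    class = "mm_params"
  )
}

#' @export
print.mm_params <- function(x, ...) {
  cat("Two-step reversible MM pathway (focal enzyme:", x$focal, "step)\n")
  cat(sprintf(
    "  S = %g mM, E = %g mM, Keq = %g / %g, Km = %g mM\n",
    x$S, x$E_end, x$Keq1, x$Keq2, x$Km
  ))
  cat(sprintf(
    "  activity ratio = %g, dilution cost = %g per mM\n",
    x$activity_ratio, x$dilution_cost
  ))
  invisible(x)
}

#' Reversible Michaelis-Menten rate law
#'
#' Net rate of a single reversible enzymatic step,
#' \deqn{v = \frac{(S - P/K_{eq}) \, V/K_f}{1 + S/K_f + P/K_r}}
#' where `S` and `P` are here the step's substrate and product
#' concentrations. The rate is linear in the enzyme activity `V` and
#' vanishes exactly at thermodynamic equilibrium (`P = S * Keq`).
#'
#' @param substrate,product Concentrations, mM.
#' @param Keq Equilibrium constant, dimensionless.
#' @param Kf,Kr Forward and reverse saturation constants, mM.
#' @param V Enzyme activity (amount times turnover), arbitrary units.
#' @return Net flux in units of `V` * mM / mM (arbitrary).
#' @export
mm_rate <- function(substrate, product, Keq, Kf, Kr, V) {
  stopifnot(Keq > 0, Kf > 0, Kr > 0)
  (substrate - product / Keq) * (V / Kf) / (1 + substrate / Kf + product / Kr)
}

mm_activities <- function(params, P) {
  if (params$focal == "first") {
    list(V1 = params$activity_ratio * P, V2 = 1 - P)
  } else {
    list(V1 = params$activity_ratio * (1 - P), V2 = P)
  }
}

#' Steady state of the two-step pathway
#'
#' For each focal-enzyme fraction `P`, solves for the intermediate
#' concentration `I` at which the flux from S to I equals the flux from I
#' to E. The flux imbalance is strictly decreasing in `I` on the bracket
#' `(E_end/Keq2, S*Keq1)` (the thermodynamic bounds on `I`), so the root is
#' unique; it is found by safeguarded bracketing to an absolute tolerance
#' of 1e-12 mM. Because both step fluxes are diluted equally, the same `I`
#' solves the system with and without the intermediate cost; the cost only
#' rescales the reported `net_flux = flux / (1 + I * c)`.
#'
#' @param params An [mm_params()] object.
#' @param P Focal-enzyme proteome fraction(s) in `(0, 1)`. Vectorized.
#' @return A tibble with columns `P`, `I` (mM), `flux`, `net_flux`.
#' @examples
#' mm_steady_state(mm_params(Km = 1), P = 0.094) # I close to 9.8 mM
#' @export
mm_steady_state <- function(params, P) {
  stopifnot(inherits(params, "mm_params"))
  check_fraction(P, "P")
  lower <- params$E_end / params$Keq2
  upper <- params$S * params$Keq1
  solve_one <- function(p) {
    act <- mm_activities(params, p)
    imbalance <- function(I) {
      mm_rate(params$S, I, params$Keq1, params$Km, params$Km, act$V1) -
        mm_rate(I, params$E_end, params$Keq2, params$Km, params$Km, act$V2)
    }
    eps <- 1e-12 * (upper - lower)
    root <- stats::uniroot(
      imbalance,
      lower = lower + eps, upper = upper - eps,
      tol = 1e-12, maxiter = 2000L
    )
    I <- root$root
    flux <- mm_rate(params$S, I, params$Keq1, params$Km, params$Km, act$V1)
    c(I = I, flux = flux)
  }
  sol <- vapply(P, solve_one, c(I = 0, flux = 0))
  I <- unname(sol["I", ])
  flux <- unname(sol["flux", ])
  tibble::tibble(
    P = P, I = I, flux = flux,
    net_flux = flux / (1 + I * params$dilution_cost)
  )
}

#' Intermediate-dilution cost coefficient
#'
#' The per-mM flux penalty `c` implied by an intermediate that is
#' `mw_ratio` times lighter than an enzyme, in a cell whose protein
#' monomers total `protein_mM` (about 4 mM for a bacterium): each mM of
#' intermediate then dilutes the proteome by `1/(mw_ratio * protein_mM)`.
#'
#' @param mw_ratio Enzyme-to-intermediate molecular weight ratio
#'   (100 for a typical metabolite, 10 for an extreme, heavy one).
#' @param protein_mM Total concentration of protein monomers, mM.
#' @return The coefficient `c` in per-mM units.
#' @examples
#' mm_dilution_cost(100) # 0.0025 per mM
#' @export
mm_dilution_cost <- function(mw_ratio = 100, protein_mM = 4) {
  stopifnot(mw_ratio > 0, protein_mM > 0)
  1 / (mw_ratio * protein_mM)
}

#' Optimize the focal enzyme's expression in the two-step pathway
#'
#' Evaluates the steady-state (dilution-corrected) flux on a grid of
#' proteome fractions and returns the flux-maximizing grid point, together
#' with the full flux curve. The default grid runs from 5e-4 to 0.5 in
#' steps of 5e-4, so reported optima are resolved to 0.05% of the
#' proteome. An optional golden-section refinement between the neighbours
#' of the grid optimum is available via `refine = TRUE`; the curve and the
#' headline `P_opt` always come from the grid.
#'
#' @param params An [mm_params()] object.
#' @param P_grid Candidate expression fractions, strictly inside `(0, 1)`.
#' @param refine If `TRUE`, also compute a continuous optimum (`P_fine`)
#'   by one-dimensional optimization between the grid neighbours.
#' @return An object of class `mm_fit` with elements `params`, `curve`
#'   (tibble: `P`, `I`, `flux`, `net_flux`), `P_opt`, `I_opt`, `flux_opt`,
#'   `net_flux_opt`, and optionally `P_fine`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' fit <- mm_optimize(mm_params(Km = 1))
#' glance(fit) # P_opt = 0.094
#' @export
mm_optimize <- function(params,
                        P_grid = seq(5e-4, 0.5, by = 5e-4),
                        refine = FALSE) {
  stopifnot(inherits(params, "mm_params"))
  check_fraction(P_grid, "P_grid")
  curve <- mm_steady_state(params, P_grid)
  i <- which.max(curve$net_flux)
  fit <- structure(
    list(
      params = params,
      curve = curve,
      P_opt = curve$P[i],
      I_opt = curve$I[i],
      flux_opt = curve$flux[i],
      net_flux_opt = curve$net_flux[i]
    ),
    class = "mm_fit"
  )
  if (refine) {
    lo <- curve$P[max(i - 1L, 1L)]
    hi <- curve$P[min(i + 1L, nrow(curve))]
    opt <- stats::optimize(
      function(p) mm_steady_state(params, p)$net_flux,
      lower = lo, upper = hi, maximum = TRUE, tol = 1e-10
    )
    fit$P_fine <- opt$maximum
  }
  fit
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf(
    "MM pathway optimum: P_opt = %.1f%% (I = %.3g mM, net flux = %.6g)\n",
    100 * x$P_opt, x$I_opt, x$net_flux_opt
  ))
  invisible(x)
}

#' @describeIn mm_optimize Flux curve as a tibble (one row per grid point).
#' @param x An `mm_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mm_fit <- function(x, ...) x$curve

#' @describeIn mm_optimize One-row summary: `P_opt`, `I_opt`, `flux_opt`,
#'   `net_flux_opt`, `Km`, `dilution_cost`.
#' @exportS3Method generics::glance
glance.mm_fit <- function(x, ...) {
  tibble::tibble(
    P_opt = x$P_opt, I_opt = x$I_opt,
    flux_opt = x$flux_opt, net_flux_opt = x$net_flux_opt,
    Km = x$params$Km, dilution_cost = x$params$dilution_cost
  )
}

#' Selection against perturbing the focal enzyme in the MM pathway
#'
#' Moves the focal enzyme's expression from the fitted optimum `P_opt` to
#' `factor * P_opt`, re-solves the steady state (the other enzyme's
#' activity is recomputed from `1 - P`, which carries the proteome
#' compensation), and reports the relative flux reduction
#' `s = 1 - net_flux(factor * P_opt) / net_flux(P_opt)` along with the
#' scale-free ratio `s / P_opt` used throughout the package.
#'
#' If the fit carries a refined optimum (`mm_optimize(refine = TRUE)`),
#' perturbations are taken around it: the grid step (5e-4, about 0.3% of
#' a typical optimum) is comparable to a 1% perturbation, so costs of
#' small changes measured from the grid argmax would be dominated by the
#' grid's placement error. Two-fold changes are insensitive to the
#' choice.
#'
#' @param fit An `mm_fit` from [mm_optimize()].
#' @param factor Multiplicative change(s) in expression, `> 0`, with
#'   `factor * P_opt < 1`. Vectorized.
#' @return A tibble with columns `factor`, `P`, `s`, `s_over_Popt`.
#' @examples
#' fit <- mm_optimize(mm_params(Km = 1))
#' mm_perturb(fit, c(0.5, 2)) # s/P_opt about 0.53 and 0.59
#' @export
mm_perturb <- function(fit, factor) {
  stopifnot(inherits(fit, "mm_fit"), all(factor > 0))
  P_base <- if (!is.null(fit$P_fine)) fit$P_fine else fit$P_opt
  P_new <- factor * P_base
  if (any(P_new >= 1)) {
    rlang::abort("`factor * P_opt` must stay below 1.")
  }
  flux_base <- mm_steady_state(fit$params, P_base)$net_flux
  ss <- mm_steady_state(fit$params, P_new)
  s <- 1 - ss$net_flux / flux_base
  tibble::tibble(
    factor = factor, P = P_new,
    s = s, s_over_Popt = s / P_base
  )
}
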