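#' Sweep selection coefficients over a cost-benefit parameter grid
#'
#' For every `(f, K)` parameter pair, computes the optimal expression
#' level, the net benefit at the optimum, and the exact selection
#' coefficient for each perturbation factor (0 = gene loss, 0.5 = halved
#' expression, 0.99 = a 1% reduction by default).
#'
#' @param grid A tibble with columns `f` and `K`, typically from
#'   [fk_grid()].
#' @param factors Perturbation factors to evaluate, each `>= 0`.
#' @return A tibble with one row per `(f, K)` pair: `f`, `K`, `P_opt`,
#'   `net_benefit_opt`, and one `s_<factor>` column per factor.
#' @examples
#' sweep_cost_benefit(fk_grid(points_per_decade = 3))
#' @export
sweep_cost_benefit <- function(grid = fk_grid(), factors = c(0, 0.5, 0.99)) {
  stopifnot(is.data.frame(grid), all(c("f", "K") %in% names(grid)))
  if (nrow(grid) == 0) rlang::abort("`grid` is empty.")
  stopifnot(all(factors >= 0))
  opt <- cb_optimum(grid$f, grid$K)
  out <- tibble::tibble(
    f = grid$f, K = grid$K,
    P_opt = opt$P_opt,
    net_benefit_opt = net_benefit(opt$P_opt, grid$f, grid$K)
  )
  for (fc in factors) {
    out[[paste0("s_", format(fc, trim = TRUE))]] <-
      selection_exact(grid$f, grid$K, fc)$s
  }
  out
}

#' Correlates of the selection against a 2-fold reduction
#'
#' Pearson correlations, on log10 scales, of the selection coefficient
#' for a chosen perturbation with (a) the optimal expression level and
#' (b) the net benefit of the protein. Both `s` and `P_opt` span orders
#' of magnitude over realistic parameter grids, which is why the
#' correlation is computed on logs. Selection against reduced expression
#' tracks the expression level far more closely than it tracks the
#' protein's importance for fitness.
#'
#' @param sweep A tibble from [sweep_cost_benefit()].
#' @param s_col Name of the selection column to correlate (default the
#'   2-fold reduction, `"s_0.5"`).
#' @return A tibble with columns `predictor` (`"P_opt"`,
#'   `"net_benefit"`), `r` (Pearson correlation of the logs), `n`.
#' @export
sweep_correlations <- function(sweep, s_col = "s_0.5") {
  stopifnot(is.data.frame(sweep), s_col %in% names(sweep))
  if (nrow(sweep) < 2) {
    rlang::abort("correlations need at least two grid points.")
  }
  ls <- log10(sweep[[s_col]])
  tibble::tibble(
    predictor = c("P_opt", "net_benefit"),
    r = c(
      stats::cor(ls, log10(sweep$P_opt)),
      stats::cor(ls, log10(sweep$net_benefit_opt))
    ),
    n = nrow(sweep)
  )
}

#' Perturbation curves for the MM pathway across settings
#'
#' Optimizes the focal enzyme's expression for each combination of `Km`
#' and dilution cost, then evaluates the relative flux loss along a range
#' of expression-change factors, in the scale-free coordinates
#' `x = P / P_opt`, `y = s / P_opt`.
#'
#' @param Km Michaelis constants (mM) to sweep.
#' @param dilution_cost Dilution coefficients (per mM) to sweep; use
#'   [mm_dilution_cost()] to derive them from molecular-weight ratios.
#' @param factors Expression-change factors along each curve.
#' @param ... Further arguments passed to [mm_params()].
#' @return A tibble with columns `Km`, `dilution_cost`, `P_opt`, `I_opt`,
#'   `factor`, `P`, `s`, `s_over_Popt`.
#' @examples
#' mm_sweep(Km = 1, factors = c(0.5, 1, 2))
#' @export
mm_sweep <- function(Km = c(0.01, 0.1, 1, 10, 100),
                     dilution_cost = 0,
                     factors = c(0.5, 2),
                     ...) {
  settings <- tidyr::expand_grid(Km = Km, dilution_cost = dilution_cost)
  purrr::pmap_dfr(settings, function(Km, dilution_cost) {
    fit <- mm_optimize(mm_params(Km = Km, dilution_cost = dilution_cost, ...))
    pert <- mm_perturb(fit, factors)
    tibble::tibble(
      Km = Km, dilution_cost = dilution_cost,
      P_opt = fit$P_opt, I_opt = fit$I_opt,
      factor = pert$factor, P = pert$P,
      s = pert$s, s_over_Popt = pert$s_over_Popt
    )
  })
}

#' Growth-model sweep over random parameter settings
#'
#' Draws `n` seeded parameter settings, optimizes the proteome allocation
#' for each, and evaluates the selection coefficients for the requested
#' expression-change factors of the focal enzyme plus the half-max
#' expression level.
#'
#' @param n Number of random settings.
#' @param seed Integer seed passed to [sample_growth_params()].
#' @param factors Expression-change factors evaluated per setting.
#' @param half_max If `TRUE` (default), also compute `K_half` and the
#'   ratio `P_opt / K_half` per setting.
#' @return A tibble with one row per setting: `setting`, `f1`, `r1`,
#'   `R_opt`, `E1_opt`, `g_opt`, one `s_<factor>` and
#'   `s_over_Popt_<factor>` column per factor, and (if requested)
#'   `K_half`, `ratio_P_K`.
#' @examples
#' growth_sweep(3, seed = 1, factors = c(0.5, 2))
#' @export
growth_sweep <- function(n = 100, seed = 1, factors = c(0.5, 2),
                         half_max = TRUE) {
  draws <- sample_growth_params(n, seed)
  purrr::map_dfr(seq_len(n), function(i) {
    fit <- growth_optimize(draws$params[[i]])
    row <- glance(fit)
    row$setting <- i
    pert <- growth_perturb(fit, factors)
    for (j in seq_along(factors)) {
      lab <- format(factors[j], trim = TRUE)
      row[[paste0("s_", lab)]] <- pert$s[j]
      row[[paste0("s_over_Popt_", lab)]] <- pert$s_over_Popt[j]
    }
    if (half_max) {
      hm <- growth_half_max(fit)
      row$K_half <- hm$K_half
      row$ratio_P_K <- hm$ratio
    }
    dplyr::relocate(row, "setting")
  })
}

#' Summarise a growth-model sweep
#'
#' Medians and ranges of the focal quantities across the settings of a
#' [growth_sweep()] table.
#'
#' @param sweep A tibble from [growth_sweep()].
#' @return A tibble with columns `quantity`, `median`, `min`, `max`.
#' @export
growth_sweep_summary <- function(sweep) {
  stopifnot(is.data.frame(sweep), nrow(sweep) >= 1)
  cols <- intersect(
    c(
      "f1", "E1_opt", "g_opt",
      grep("^s_", names(sweep), value = TRUE),
      "K_half", "ratio_P_K"
    ),
    names(sweep)
  )
  purrr::map_dfr(cols, function(cl) {
    tibble::tibble(
      quantity = cl,
      median = stats::median(sweep[[cl]]),
      min = min(sweep[[cl]]),
      max = max(sweep[[cl]])
    )
  })
}

#' Write a sweep table as CSV with a provenance header
#'
#' Writes comment lines recording the generating seed and package
#' version, followed by the table in plain CSV (comma separator, `.`
#' decimal, header row, no row names).
#'
#' @param data A data frame.
#' @param path Output file path.
#' @param seed The seed used to generate `data` (recorded in the header;
#'   `NA` for deterministic tables).
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(data, path, seed = NA) {
  stopifnot(is.data.frame(data))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf(
    "# exprsel %s | seed: %s",
    as.character(utils::packageVersion("exprsel")), as.character(seed)
  ), con)
  utils::write.csv(data, con, row.names = FALSE)
  invisible(path)
}
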