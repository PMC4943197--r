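#' Random parameter settings for the growth model
#'
#' Draws seeded random `(f, r)` settings following the study design of the
#' growth model: the focal amino acid's usage fraction is
#' `f1 = 2^N1 / sum(2^Ni)` with `N` a vector of 20 independent standard
#' normals, the other 19 fractions share the remainder equally; the focal
#' enzyme rate is drawn from the same distribution using an independent
#' normal vector and the rates are rescaled so their mean is exactly 5
#' (`r1 = 100 * 2^M1 / sum(2^Mi)`, others equal). Draws are deterministic
#' given `seed` (Mersenne-Twister via [set.seed()]).
#'
#' Across many draws `f1` spans roughly 0.01 to 0.4 with a median near
#' 0.04: most amino acids are a few percent of usage, a few dominate.
#'
#' @param n Number of parameter settings to draw.
#' @param seed Integer seed controlling the draw.
#' @return A tibble with `n` rows and columns `setting`, `f1`, `r1`, and a
#'   list-column `params` of [growth_params()] objects.
#' @examples
#' draws <- sample_growth_params(5, seed = 1)
#' draws$f1
#' @export
sample_growth_params <- function(n, seed) {
  stopifnot(n >= 1, is.numeric(seed), length(seed) == 1)
  set.seed(as.integer(seed))
  draws <- purrr::map(seq_len(n), function(i) {
    N <- stats::rnorm(20)
    f1 <- 2^N[1] / sum(2^N)
    M <- stats::rnorm(20)
    r1 <- 100 * 2^M[1] / sum(2^M)
    growth_params(
      f = c(f1, rep((1 - f1) / 19, 19)),
      r = c(r1, rep((100 - r1) / 19, 19))
    )
  })
  tibble::tibble(
    setting = seq_len(n),
    f1 = purrr::map_dbl(draws, ~ .x$f[1]),
    r1 = purrr::map_dbl(draws, ~ .x$r[1]),
    params = draws
  )
}

#' Log-spaced (f, K) parameter grid for cost-benefit sweeps
#'
#' Generates a log-spaced grid of maximum benefits `f` and half-max
#' expression levels `K`, keeps the combinations where the protein is
#' net-beneficial (`K < f`), and filters to those whose optimal expression
#' level `P_opt = sqrt(K f) - K` falls inside `P_opt_range`. The default
#' filter, 5e-6 to 0.03, matches the realistic range of expression of
#' proteins that matter for fitness in bacteria and yeast; the default
#' `K` lower bound 2e-7 is one protein copy per bacterial cell.
#'
#' @param f_range Range of maximum benefits (length 2).
#' @param K_range Range of half-max expression levels (length 2).
#' @param points_per_decade Grid density on each log10 axis.
#' @param P_opt_range Retained optimal-expression window (length 2).
#' @return A tibble with columns `f`, `K`, `P_opt`, `s_opt`, sorted by
#'   `f` then `K`. Errors if the filter removes every grid point.
#' @examples
#' nrow(fk_grid())
#' @export
fk_grid <- function(f_range = c(1e-5, 1),
                    K_range = c(2e-7, 1e-1),
                    points_per_decade = 10,
                    P_opt_range = c(5e-6, 0.03)) {
  stopifnot(
    length(f_range) == 2, length(K_range) == 2, length(P_opt_range) == 2,
    all(f_range > 0), all(K_range > 0), points_per_decade >= 1
  )
  log_seq <- function(rng, ppd) {
    lo <- log10(rng[1]); hi <- log10(rng[2])
    if (hi <= lo) return(rng[1])
    10^seq(lo, hi, length.out = max(2L, ceiling((hi - lo) * ppd) + 1L))
  }
  grid <- tidyr::expand_grid(
    f = log_seq(f_range, points_per_decade),
    K = log_seq(K_range, points_per_decade)
  )
  grid <- dplyr::filter(grid, .data$K < .data$f)
  if (nrow(grid) == 0) {
    rlang::abort("no grid point satisfies K < f; widen the ranges.")
  }
  opt <- cb_optimum(grid$f, grid$K)
  out <- dplyr::filter(
    opt,
    .data$P_opt >= P_opt_range[1], .data$P_opt <= P_opt_range[2]
  )
  if (nrow(out) == 0) {
    rlang::abort("the P_opt filter removed every grid point; widen `P_opt_range`.")
  }
  out
}
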