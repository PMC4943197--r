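#' Strength of selection relative to drift
#'
#' The product `Ne * |s|` decides whether selection on a variant
#' overcomes genetic drift: under the nearly neutral theory a variant is
#' under effective selection when `Ne * |s| > 1`.
#'
#' @param Ne Effective population size(s), individuals. Vectorized.
#' @param s Selection coefficient(s); the magnitude is used.
#' @return A tibble with columns `Ne`, `s`, `Ne_s`, and logical
#'   `strong_selection` (`Ne_s > 1`).
#' @examples
#' ne_s(1e6, 2.5e-6) # Ne*s = 2.5: selected against
#' @export
ne_s <- function(Ne, s) {
  n <- vctrs_recycle_common(Ne = Ne, s = s)
  stopifnot(all(n$Ne > 0))
  prod <- n$Ne * abs(n$s)
  tibble::tibble(Ne = n$Ne, s = n$s, Ne_s = prod, strong_selection = prod > 1)
}

#' Mutational target of a gene
#'
#' Total rate of inactivating mutations for a gene, approximated as the
#' per-nucleotide mutation rate times the coding length: a 1 kb gene with
#' `mu = 2e-10` per nucleotide is inactivated at about `2e-7` per
#' generation — which also bounds the mutational-robustness benefit of
#' keeping a duplicate copy.
#'
#' @param gene_length Coding length(s), nucleotides. Vectorized.
#' @param mu_nt Per-nucleotide mutation rate, per generation.
#' @return Numeric vector of per-generation inactivation rates.
#' @examples
#' gene_mutational_target(1000, 2e-10) # 2e-7
#' @export
gene_mutational_target <- function(gene_length, mu_nt) {
  stopifnot(all(gene_length >= 0), all(mu_nt >= 0))
  gene_length * mu_nt
}

#' Selection needed to maintain an allele against biased mutation
#'
#' A gene is far easier to inactivate by mutation than to restore: with a
#' mutational-target ratio around 1000 (one inactivating site per coding
#' nucleotide versus a single reverting change), the selection coefficient
#' needed to keep the functional allele in the population rises from the
#' drift threshold `1/Ne` by a factor `ln(ratio)` — about 7-fold for
#' `ratio = 1000`.
#'
#' @param Ne Effective population size.
#' @param mutation_rate_ratio Forward (inactivating) to backward
#'   (restoring) mutation-rate ratio, `>= 1`. Vectorized. A ratio of 1
#'   returns 0: the log factor vanishes and maintenance is set by drift
#'   alone.
#' @return A tibble with columns `Ne`, `ratio`, `multiplier`
#'   (`ln(ratio)`), `s_required` (`ln(ratio)/Ne`).
#' @examples
#' maintenance_threshold(1e6, 1000) # s_required ~7e-6
#' @export
maintenance_threshold <- function(Ne, mutation_rate_ratio) {
  n <- vctrs_recycle_common(Ne = Ne, ratio = mutation_rate_ratio)
  stopifnot(all(n$Ne > 0), all(n$ratio >= 1))
  tibble::tibble(
    Ne = n$Ne, ratio = n$ratio,
    multiplier = log(n$ratio),
    s_required = log(n$ratio) / n$Ne
  )
}

#' Equilibrium frequency of a deleterious allele
#'
#' Mutation-selection balance: a deleterious allele recurrently produced
#' at rate `mu` and removed by selection `s` settles at frequency about
#' `mu / s` (capped at 1). For loss of a typical gene (`mu ~ 2e-7`,
#' `s` of order 1) this is around `1e-7`.
#'
#' @param mu Mutation rate(s) toward the allele, per generation.
#'   Vectorized.
#' @param s Selection coefficient(s) against the allele, `> 0`.
#' @return Numeric vector of equilibrium frequencies in `[0, 1]`.
#' @examples
#' deleterious_frequency(2e-7, 2) # 1e-7
#' @export
deleterious_frequency <- function(mu, s) {
  n <- vctrs_recycle_common(mu = mu, s = s)
  stopifnot(all(n$mu >= 0))
  if (any(n$s <= 0)) {
    rlang::abort("`s` must be positive: no mutation-selection balance without selection.")
  }
  pmin(n$mu / n$s, 1)
}

#' Worked population-genetic arithmetic for expression-level selection
#'
#' Assembles the package's headline population-genetic quantities into one
#' tidy table: the selection against a 2-fold expression change for a
#' minimally expressed protein (`s >= 0.5 * P` with `P = 5e-6`), its
#' `Ne * s` product, the mutational-robustness benefit of a gene
#' duplicate, the maintenance threshold under biased mutation, and the
#' mutation-selection equilibrium frequency for gene loss.
#'
#' @param Ne Effective population size.
#' @param P_min Minimum expression fraction of proteins that matter for
#'   fitness.
#' @param gene_length Typical coding length, nucleotides.
#' @param mu_nt Per-nucleotide mutation rate, per generation.
#' @param s_loss Selection coefficient against complete loss of a gene
#'   that matters for fitness (order 1).
#' @return A tibble with columns `quantity`, `value`, `units`.
#' @examples
#' popgen_report()
#' @export
popgen_report <- function(Ne = 1e6, P_min = 5e-6,
                          gene_length = 1000, mu_nt = 2e-10, s_loss = 2) {
  s_twofold <- 0.5 * P_min
  dup_rate <- gene_mutational_target(gene_length, mu_nt)
  tibble::tibble(
    quantity = c(
      "s for 2-fold change at minimum expression",
      "Ne * s for that change",
      "gene inactivation rate (duplication benefit bound)",
      "maintenance threshold s under 1000-fold mutation bias",
      "equilibrium frequency of gene-loss alleles"
    ),
    value = c(
      s_twofold,
      ne_s(Ne, s_twofold)$Ne_s,
      dup_rate,
      maintenance_threshold(Ne, gene_length)$s_required,
      deleterious_frequency(dup_rate, s_loss)
    ),
    units = c(
      "selection coefficient", "dimensionless", "per generation",
      "selection coefficient", "allele frequency"
    )
  )
}
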