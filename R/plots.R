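#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the flux curve of an MM pathway fit
#'
#' Net steady-state flux against the focal enzyme's proteome fraction,
#' with the grid optimum marked.
#'
#' @param object An `mm_fit` from [mm_optimize()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mm_fit <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$P, y = .data$net_flux)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$P_opt, linetype = "dashed") +
    ggplot2::labs(
      x = "focal enzyme fraction of proteome",
      y = "steady-state flux (dilution-corrected)",
      title = sprintf(
        "Km = %g mM, dilution cost = %g per mM: P_opt = %.1f%%",
        object$params$Km, object$params$dilution_cost, 100 * object$P_opt
      )
    )
}

#' Plot perturbation cost curves in scale-free coordinates
#'
#' Relative fitness loss per unit of optimal expression (`s / P_opt`)
#' against the expression-change factor (`P / P_opt`), one curve per
#' pathway setting; the natural way to compare selection across models
#' whose optima differ by orders of magnitude.
#'
#' @param data A tibble with columns `factor` and `s_over_Popt`, e.g.
#'   from [mm_sweep()]; any additional `Km` / `dilution_cost` columns are
#'   mapped to colour and linetype.
#' @return A ggplot object.
#' @export
plot_perturbation <- function(data) {
  stopifnot(all(c("factor", "s_over_Popt") %in% names(data)))
  p <- ggplot2::ggplot(
    data,
    ggplot2::aes(x = .data$factor, y = .data$s_over_Popt)
  )
  if ("Km" %in% names(data)) {
    p <- p + ggplot2::aes(colour = factor(.data$Km))
  }
  if ("dilution_cost" %in% names(data)) {
    p <- p + ggplot2::aes(linetype = factor(.data$dilution_cost))
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "expression relative to optimum (P / P_opt)",
      y = "fitness loss per unit expression (s / P_opt)",
      colour = "Km (mM)", linetype = "dilution cost"
    )
}

#' Plot a growth-model sweep as a point cloud
#'
#' The fitness cost of halving and doubling the focal enzyme's
#' expression, per setting, against the optimal expression level
#' (log-log), with the quadratic lower bound and the rate-limiting
#' reference as dashed lines.
#'
#' @param sweep A tibble from [growth_sweep()] run with factors 0.5
#'   and 2.
#' @return A ggplot object.
#' @export
plot_growth_sweep <- function(sweep) {
  stopifnot(all(c("E1_opt", "s_0.5", "s_2") %in% names(sweep)))
  long <- tidyr::pivot_longer(
    sweep[, c("E1_opt", "s_0.5", "s_2")],
    cols = c("s_0.5", "s_2"),
    names_to = "change", values_to = "s"
  )
  long$change <- ifelse(long$change == "s_0.5", "halved", "doubled")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$E1_opt, y = .data$s,
    colour = .data$change
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = log10(0.25), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "optimal expression of focal enzyme (P_opt)",
      y = "fitness reduction (s)",
      colour = "2-fold change"
    )
}
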