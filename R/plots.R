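#' Plot integrated heats against injection number
#'
#' @param data Tibble with `injection` and `heat` (cal), e.g. from
#'   [simulate_experiment()] or [read_heats()].
#' @param model Optional numeric vector of model heats (cal) drawn as a
#'   line.
#' @return A ggplot object (heats in ucal).
#' @export
plot_heats <- function(data, model = NULL) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$injection,
                                          y = .data$heat * 1e6)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "injection", y = "integrated heat (μcal)")
  if (!is.null(model))
    p <- p + ggplot2::geom_line(
      data = tibble(injection = data$injection, heat = model),
      colour = "firebrick")
  p
}

#' Marginal posterior histograms of a Bayesian fit
#'
#' One panel per parameter (dG, dH in kcal/mol; dH0 and sigma in ucal;
#' concentrations in mM), with the shortest credible interval marked.
#'
#' @param object An `itc_bayes_fit`.
#' @param level Credible level for the interval bars.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.itc_bayes_fit <- function(object, level = 0.95, ...) {
  draws <- object$samples |>
    mutate(dH0 = .data$dH0 * 1e6, sigma = .data$sigma * 1e6,
           Ls = .data$Ls * 1e3, R0 = .data$R0 * 1e3) |>
    select("dG", "dH", "dH0", "Ls", "R0", "sigma") |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "parameter")
  ci <- draws |>
    group_by(.data$parameter) |>
    summarise(shortest_credible_interval(.data$value, level)[, c("lower", "upper")],
              .groups = "drop")
  ggplot2::ggplot(draws, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey60") +
    ggplot2::geom_errorbarh(
      data = ci,
      ggplot2::aes(xmin = .data$lower, xmax = .data$upper, y = 0),
      inherit.aes = FALSE, height = 0, linewidth = 1.2, colour = "firebrick") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "draws")
}

#' Plot running credible-interval convergence
#'
#' Running upper and lower interval bounds per chain against the number of
#' samples, one panel per parameter.
#'
#' @param report An `itc_convergence` from [convergence_report()].
#' @return A ggplot object.
#' @export
plot_convergence <- function(report) {
  long <- tidyr::pivot_longer(report$running, c("lower", "upper"),
                              names_to = "bound")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data$value,
                                     group = interaction(.data$chain,
                                                         .data$bound))) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "stored samples",
                  y = sprintf("running %.0f%% interval bounds",
                              report$level * 100))
}

#' Plot an interval-coverage calibration curve
#'
#' Observed containment rate against nominal level, with bootstrap error
#' bars; a calibrated method lies on the diagonal.
#'
#' @param curve Tibble from [coverage_curve()], optionally with a grouping
#'   column `method`.
#' @return A ggplot object (axes in %).
#' @export
plot_coverage <- function(curve) {
  aes <- if ("method" %in% names(curve))
    ggplot2::aes(x = .data$level * 100, y = .data$observed * 100,
                 colour = .data$method)
  else
    ggplot2::aes(x = .data$level * 100, y = .data$observed * 100)
  ggplot2::ggplot(curve, aes) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = (.data$observed - .data$boot_sd) * 100,
                   ymax = (.data$observed + .data$boot_sd) * 100),
      width = 1.5) +
    ggplot2::coord_cartesian(xlim = c(0, 100), ylim = c(0, 100)) +
    ggplot2::labs(x = "nominal level (%)", y = "observed rate (%)")
}

#' Heat-map of a pairwise divergence matrix
#'
#' @param mat Matrix from [kl_matrix()] (typically `log = TRUE`).
#' @return A ggplot object.
#' @export
plot_kl_matrix <- function(mat) {
  df <- as.data.frame(as.table(mat))
  names(df) <- c("row", "col", "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "ln KL")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
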