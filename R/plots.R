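#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Rating ladder plot for a walkrank fit
#'
#' Teams ordered strongest to weakest, with jackknife error bars when the
#' fit carries them.
#'
#' @param object A `walkrank` object.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot walkrank
#' @export
autoplot.walkrank <- function(object, ...) {
  d <- tidy(object)
  d$team <- factor(d$team, levels = rev(d$team))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$rating, y = .data$team)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "combined rating (strength - weakness occupancy)",
                  y = NULL) +
    ggplot2::theme_minimal()
  if ("std.error" %in% names(d)) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$rating - .data$std.error,
                   xmax = .data$rating + .data$std.error),
      height = 0.25
    )
  }
  p
}

#' Weekly prediction-accuracy curves
#'
#' @param series Output of [weekly_accuracy()] (one or more methods).
#' @return A ggplot of accuracy against round, one line per method.
#' @export
plot_weekly_accuracy <- function(series) {
  ggplot2::ggplot(series, ggplot2::aes(x = .data$round, y = .data$accuracy,
                                       colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "round", y = "prediction accuracy") +
    ggplot2::theme_minimal()
}

#' Rank-convergence diagnostics
#'
#' Line crossings per round with the fitted exponential decay (top), and
#' the Spearman correlation of each round's ranking with the final one.
#'
#' @param series Output of [src_series()].
#' @param fit Optional `exp_fit` for the crossings panel.
#' @param threshold Convergence threshold drawn on the SRC panel.
#' @return A list of two ggplots: `crossings` and `src`.
#' @export
plot_convergence <- function(series, fit = NULL, threshold = 0.9) {
  pc <- ggplot2::ggplot(dplyr::filter(series, !is.na(.data$crossings)),
                        ggplot2::aes(x = .data$round, y = .data$crossings)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::labs(x = "round", y = "line crossings") +
    ggplot2::theme_minimal()
  if (!is.null(fit) && !fit$degenerate) {
    grid <- tibble::tibble(round = seq(min(series$round), max(series$round),
                                       length.out = 200))
    grid$crossings <- fit$a * exp(-fit$b * grid$round)
    pc <- pc + ggplot2::geom_line(data = grid, colour = "firebrick")
  }
  ps <- ggplot2::ggplot(dplyr::filter(series, !is.na(.data$src)),
                        ggplot2::aes(x = .data$round, y = .data$src)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "round", y = "Spearman correlation with final ranking") +
    ggplot2::theme_minimal()
  list(crossings = pc, src = ps)
}
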