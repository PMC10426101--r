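#' Coefficient plot of an averaged path model
#'
#' Dot-and-interval plot of the standardised averaged path coefficients;
#' paths whose CI spans zero are shown hollow.
#'
#' @param object An `averaged_model`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.averaged_model <- function(object, ...) {
  d <- object$paths
  if (!nrow(d)) return(ggplot2::ggplot())
  d$path <- paste(d$from, "→", d$to)
  d$path <- stats::reorder(d$path, d$coefficient)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$coefficient, y = .data$path)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.15
    ) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$excluded,
                                     colour = .data$coefficient < 0),
                        size = 2.5) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                name = "CI spans 0") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "standardised path coefficient (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.averaged_model
#' @export
autoplot.phylo_path <- function(object, ...) {
  autoplot.averaged_model(object$averaged, ...)
}

#' CICc profile of the scored model space
#'
#' Sorted CICc values with the retention window shaded.
#'
#' @param object A `model_scores` tibble.
#' @param threshold Retention window to mark (default 2).
#' @param max_shown Number of top models to draw.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.model_scores <- function(object, threshold = 2, max_shown = 500, ...) {
  d <- object[is.na(object$unscored), , drop = FALSE]
  d <- utils::head(d[order(d$CICc), ], max_shown)
  d$rank <- seq_len(nrow(d))
  best <- min(d$CICc)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$CICc)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = best,
                      ymax = best + threshold, alpha = 0.15,
                      fill = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "model rank", y = "CICc") +
    ggplot2::theme_minimal()
}

#' Forest plot of a bivariate screen table
#'
#' @param screen Output of [bivariate_screen()].
#' @return A ggplot object.
#' @export
plot_screen <- function(screen) {
  d <- screen[is.na(screen$error), , drop = FALSE]
  d$variable <- stats::reorder(d$variable, -d$p.value)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$variable)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$std.error,
                   xmax = .data$estimate + 1.96 * .data$std.error),
      height = 0.15
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$p.value < 0.05),
                        size = 2.5) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "black"),
                                 name = "p < 0.05") +
    ggplot2::labs(x = "coefficient (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
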