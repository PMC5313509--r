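#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Accuracy-vs-stability diagram of internal criterion points
#'
#' Plots the internal mean accuracy against a stability measure for every
#' hyperparameter combination of one or more external folds, the diagram
#' the distance-to-(1,1) selection criteria read.
#'
#' @param points tibble from [internal_evaluate()] or the `diagrams`
#'   element of a `selection_result`.
#' @param stability `"oc"` (corrected overlap) or `"corr"` (correlation).
#' @return A ggplot object.
#' @export
plot_stability_diagram <- function(points, stability = c("oc", "corr")) {
  stability <- match.arg(stability)
  lab <- if (stability == "oc") "mean corrected overlap" else "mean correlation"
  pts <- dplyr::filter(points, .data$ok)
  aes <- if ("test_subject" %in% names(pts)) {
    ggplot2::aes(x = .data[[stability]], y = .data$accuracy,
                 group = .data$test_subject, colour = .data$test_subject)
  } else {
    ggplot2::aes(x = .data[[stability]], y = .data$accuracy)
  }
  ggplot2::ggplot(pts, aes) +
    ggplot2::geom_path(alpha = 0.6) +
    ggplot2::geom_point(size = 1) +
    ggplot2::annotate("point", x = 1, y = 1, shape = 3, size = 3) +
    ggplot2::labs(x = lab, y = "mean internal accuracy",
                  colour = "held-out\nsubject") +
    ggplot2::theme_minimal()
}

#' @rdname plot_stability_diagram
#' @param object a `selection_result`.
#' @param ... passed to [plot_stability_diagram()].
#' @export
autoplot.selection_result <- function(object, stability = c("oc", "corr"),
                                      ...) {
  stability <- match.arg(stability)
  plot_stability_diagram(object$diagrams, stability) +
    ggplot2::ggtitle(sprintf("%s: internal accuracy vs stability",
                             toupper(object$family)))
}

#' Coefficient-map slice plot
#'
#' Tile plot of an axial slice of a fitted coefficient map.
#'
#' @param object a `decoder_fit`.
#' @param slice z-index of the slice (default: middle).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.decoder_fit <- function(object, slice = NULL, ...) {
  grid <- object$grid
  if (is.null(slice)) slice <- ceiling(grid$shape[3] / 2)
  df <- tidy.decoder_fit(object)
  df <- dplyr::filter(df, .data$z == slice)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$beta)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s coefficients, slice z = %d",
                                  toupper(object$spec$family), slice)) +
    ggplot2::theme_minimal()
}
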