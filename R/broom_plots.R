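# Tidiers and plots for fitted models and metric reports.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training trace of a fitted model
#'
#' @param x a `dd_model`.
#' @param ... unused.
#' @return long tibble with columns `epoch`, `component`, `value`.
#' @method tidy dd_model
#' @export
tidy.dd_model <- function(x, ...) {
  if (!nrow(x$trace)) return(tibble::tibble(epoch = integer(),
                                            component = character(),
                                            value = numeric()))
  tidyr::pivot_longer(x$trace, -"epoch", names_to = "component",
                      values_to = "value")
}

#' One-row model summary
#'
#' @param x a `dd_model`.
#' @param ... unused.
#' @return tibble with layer count, atom counts, class count, epochs run and
#'   final objective.
#' @method glance dd_model
#' @export
glance.dd_model <- function(x, ...) {
  tibble::tibble(
    n_layers = x$stack$n_layers,
    n_atoms = paste(vapply(x$stack$dictionaries, ncol, 1L), collapse = "/"),
    n_classes = length(x$classes),
    n_train = ncol(x$B),
    epochs = if (nrow(x$trace)) max(x$trace$epoch) else 0L,
    objective = if (nrow(x$trace)) x$trace$total[nrow(x$trace)] else NA_real_
  )
}

#' Plot the objective trace of a fitted model
#'
#' One line per objective component (log10 y scale) across epochs.
#'
#' @param object a `dd_model`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot dd_model
#' @export
autoplot.dd_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "objective component",
                  title = "Training objective trace") +
    ggplot2::theme_minimal()
}

#' Plot a metric report's confusion matrix
#'
#' @param object a `dd_metrics`.
#' @param class_names optional class labels for the axes.
#' @param ... unused.
#' @return a ggplot heatmap of the row-normalised confusion matrix.
#' @method autoplot dd_metrics
#' @export
autoplot.dd_metrics <- function(object, class_names = NULL, ...) {
  conf <- object$confusion
  C <- nrow(conf)
  nm <- class_names %||% sprintf("class_%d", seq_len(C) - 1L)
  df <- tidyr::expand_grid(true = factor(nm, levels = rev(nm)),
                           predicted = factor(nm, levels = nm))
  df$rate <- as.vector(t(conf[rev(seq_len(C)), , drop = FALSE]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rate))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "predicted", y = "true",
                  title = "Row-normalised confusion matrix") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
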