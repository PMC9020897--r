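#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a feature-importance ranking
#'
#' @param x A `gini_importance` tibble.
#' @param ... Unused.
#' @return Tibble with `feature`, `importance`, `rank`.
#' @export
tidy.gini_importance <- function(x, ...) {
  tibble::tibble(feature = x$feature, importance = x$importance,
                 rank = seq_len(nrow(x)))
}

#' @rdname tidy.gini_importance
#' @param object A `gini_importance` tibble.
#' @export
glance.gini_importance <- function(x, ...) {
  tibble::tibble(n_features = nrow(x),
                 top_feature = x$feature[which.max(x$importance)],
                 top_importance = max(x$importance))
}

#' Plot a feature-importance ranking
#'
#' Horizontal bar chart of normalised Gini importances, most important at
#' the top.
#'
#' @param object A `gini_importance` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gini_importance <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$importance,
    y = stats::reorder(.data$feature, .data$importance)
  )) +
    ggplot2::geom_col(fill = "#3b6fb6") +
    ggplot2::labs(x = "normalised Gini importance", y = NULL,
                  title = "Random-forest feature importance") +
    ggplot2::theme_minimal()
}

#' Tidy a trained LSTM
#'
#' One row per learnable parameter group with its size and L2 norm —
#' a quick view of where the model's weight mass sits.
#'
#' @param x A `cardio_lstm`.
#' @param ... Unused.
#' @return Tibble with `group`, `n_params`, `l2_norm`.
#' @export
tidy.cardio_lstm <- function(x, ...) {
  tibble::tibble(
    group = names(x$params),
    n_params = vapply(x$params, length, integer(1)),
    l2_norm = vapply(x$params, function(p) sqrt(sum(p^2)), numeric(1))
  )
}

#' @rdname tidy.cardio_lstm
#' @export
glance.cardio_lstm <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    hidden_dim = x$hidden_dim,
    n_features = length(x$features),
    optimizer = x$optimizer,
    steps = x$steps,
    final_loss = if (nrow(x$history)) x$history$loss[nrow(x$history)]
      else NA_real_
  )
}

#' Plot an LSTM training trajectory
#'
#' Training loss per optimizer step, with any held-out checkpoint losses
#' overlaid as points.
#'
#' @param object A `cardio_lstm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cardio_lstm <- function(object, ...) {
  p <- ggplot2::ggplot(object$history,
                       ggplot2::aes(x = .data$step, y = .data$loss)) +
    ggplot2::geom_line(colour = "#3b6fb6", alpha = 0.8) +
    ggplot2::labs(x = "optimizer step", y = "binary cross-entropy",
                  title = "Training loss") +
    ggplot2::theme_minimal()
  if (nrow(object$checkpoints) > 0) {
    p <- p + ggplot2::geom_point(
      data = object$checkpoints, colour = "#c23b22", size = 2
    )
  }
  p
}

#' Tidy / summarise a pipeline run
#'
#' `tidy()` returns the held-out metrics in long form; `glance()` a single
#' row with the metrics and stage row counts.
#'
#' @param x A `cardio_run` from [run_pipeline()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cardio_run <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @rdname tidy.cardio_run
#' @export
glance.cardio_run <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(rows_raw = x$rows$raw, rows_clean = x$rows$cleaned,
                   n_selected = length(x$selected)),
    x$metrics
  )
}

#' Plot an optimizer comparison
#'
#' Held-out accuracy and loss against optimizer step, one line per
#' optimizer.
#'
#' @param object An `optimizer_comparison` from [compare_optimizers()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.optimizer_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[c("optimizer", "step", "accuracy", "loss")],
    c("accuracy", "loss"), names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value,
                                     colour = .data$optimizer)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "optimizer step", y = NULL,
                  title = "Optimizer comparison") +
    ggplot2::theme_minimal()
}

#' Plot a correlation matrix as a heat map
#'
#' Tile map of a [pearson_matrix()] with the coefficient printed in each
#' cell.
#'
#' @param m Symmetric correlation matrix.
#' @return A ggplot.
#' @export
plot_correlation <- function(m) {
  df <- tibble::as_tibble(as.table(m), .name_repair = "minimal")
  names(df) <- c("a", "b", "r")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 2.6) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166ac",
                                  mid = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
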