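# broom-style tidiers and ggplot2 methods for fitted objects and reports.

#' Tidy a training run
#'
#' @param x A `stress_fit` from [train_model()].
#' @param ... Unused.
#' @return Per-epoch tibble: `epoch`, `train_loss`, `val_accuracy`,
#'   `val_macro_f1`.
#' @export
tidy.stress_fit <- function(x, ...) {
  x$history
}

#' @rdname tidy.stress_fit
#' @return `glance()`: one-row tibble with the fold-level metrics, epoch
#'   count, model name and parameter count.
#' @export
glance.stress_fit <- function(x, ...) {
  tibble(model = x$model$name,
         epochs = nrow(x$history),
         accuracy = x$metrics$accuracy,
         f1 = x$metrics$f1,
         final_val_accuracy = x$history$val_accuracy[nrow(x$history)],
         n_params = n_params(x$model),
         n_train = x$n_train, n_val = x$n_val)
}

#' Tidy an evaluation report
#'
#' @param x A `stress_eval` from [evaluate_suite()].
#' @param ... Unused.
#' @return Per-fold results tibble.
#' @export
tidy.stress_eval <- function(x, ...) {
  x$results
}

#' @rdname tidy.stress_eval
#' @export
glance.stress_eval <- function(x, ...) {
  x$summary
}

#' Plot a training run
#'
#' @param object A `stress_fit`.
#' @param ... Unused.
#' @return A ggplot of per-epoch validation accuracy and macro-F1.
#' @export
autoplot.stress_fit <- function(object, ...) {
  df <- object$history |>
    tidyr::pivot_longer(c("val_accuracy", "val_macro_f1"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL,
                  title = sprintf("%s validation metrics", object$model$name)) +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report
#'
#' @param object A `stress_eval`.
#' @param ... Unused.
#' @return A ggplot of accuracy and macro-F1 by signal combination and
#'   model.
#' @export
autoplot.stress_eval <- function(object, ...) {
  df <- object$summary |>
    tidyr::pivot_longer(c("accuracy", "f1"), names_to = "metric",
                        values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$combination, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~model) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "signal combination", y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a (fold-averaged) confusion matrix
#'
#' @param cm Square confusion matrix (true classes in rows).
#' @param title Optional plot title.
#' @return A ggplot heat map with cell counts.
#' @export
plot_confusion <- function(cm, title = NULL) {
  df <- as.data.frame(as.table(cm))
  names(df) <- c("true", "pred", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$count, 1))) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted class", y = "true class", title = title) +
    ggplot2::theme_minimal()
}
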