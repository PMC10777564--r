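#' Plot training and validation loss curves
#'
#' @param object An `sfgcn_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sfgcn_fit
#' @export
autoplot.sfgcn_fit <- function(object, ...) {
  log <- tidy(object)
  long <- log |>
    tidyr::pivot_longer(c("train_loss", "val_loss"),
                        names_to = "series", values_to = "loss") |>
    filter(!is.na(.data$loss))
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$loss,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "weighted cross-entropy",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' @param object An `sfgcn_cv`.
#' @param metrics Which panel columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sfgcn_cv
#' @export
autoplot.sfgcn_cv <- function(object, metrics = c("ACC", "AUC", "MCC", "F1"),
                              ...) {
  long <- tidy(object) |>
    tidyr::pivot_longer(dplyr::all_of(metrics),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(factor(.data$fold), .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "fold", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a grid experiment as an accuracy tile map
#'
#' @param object An `sfgcn_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sfgcn_grid
#' @export
autoplot.sfgcn_grid <- function(object, ...) {
  tab <- tidy(object)
  ggplot2::ggplot(tab, ggplot2::aes(factor(.data$k), factor(.data$d),
                                    fill = .data$ACC)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.3f%s", .data$ACC,
                      ifelse(.data$selected, " *", "")))) +
    ggplot2::labs(x = "k", y = "d", fill = "mean ACC") +
    ggplot2::theme_minimal()
}

#' Plot node occurrence frequencies of a sequence feature graph
#'
#' @param object An `sfg`.
#' @param top_n Show only the `top_n` most frequent k-mers.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sfg
#' @export
autoplot.sfg <- function(object, top_n = 20, ...) {
  tab <- tibble(kmer = object$kmer_labels,
                feature = object$node_features) |>
    arrange(desc(.data$feature)) |>
    head(top_n)
  ggplot2::ggplot(tab, ggplot2::aes(stats::reorder(.data$kmer, .data$feature),
                                    .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "occurrence frequency") +
    ggplot2::theme_minimal()
}
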