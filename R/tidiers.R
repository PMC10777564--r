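#' Tidy a fitted classifier's training log
#'
#' @param x An `sfgcn_fit`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `train_loss`, `val_loss`, `val_acc`.
#' @method tidy sfgcn_fit
#' @export
tidy.sfgcn_fit <- function(x, ...) {
  x$log
}

#' One-row summary of a fitted classifier
#'
#' @param x An `sfgcn_fit`.
#' @param ... Unused.
#' @return One-row tibble: encoder and depth settings, parameter count,
#'   epochs run, final train/validation loss and validation accuracy.
#' @method glance sfgcn_fit
#' @export
glance.sfgcn_fit <- function(x, ...) {
  last <- if (nrow(x$log) > 0) x$log[nrow(x$log), ] else {
    tibble(train_loss = NA_real_, val_loss = NA_real_, val_acc = NA_real_)
  }
  tibble(k = x$encoder$k, d = x$encoder$d,
         n_gcn_layers = x$model$n_gcn_layers,
         n_parameters = n_params(x$params),
         epochs = nrow(x$log),
         train_loss = last$train_loss,
         val_loss = last$val_loss,
         val_acc = last$val_acc)
}

#' Tidy per-fold cross-validation panels
#'
#' @param x An `sfgcn_cv`.
#' @param ... Unused.
#' @return Tibble with one metric-panel row per fold.
#' @method tidy sfgcn_cv
#' @export
tidy.sfgcn_cv <- function(x, ...) {
  x$folds
}

#' Mean cross-validation panel
#'
#' @param x An `sfgcn_cv`.
#' @param ... Unused.
#' @return One-row tibble of fold-mean metrics.
#' @method glance sfgcn_cv
#' @export
glance.sfgcn_cv <- function(x, ...) {
  x$mean
}

#' Tidy a grid experiment's ranked table
#'
#' @param x An `sfgcn_grid`.
#' @param ... Unused.
#' @return Ranked tibble of (k, d) pairs and mean metrics.
#' @method tidy sfgcn_grid
#' @export
tidy.sfgcn_grid <- function(x, ...) {
  x$table
}

#' Selected pair of a grid experiment
#'
#' @param x An `sfgcn_grid`.
#' @param ... Unused.
#' @return One-row tibble: the selected pair and its mean metrics.
#' @method glance sfgcn_grid
#' @export
glance.sfgcn_grid <- function(x, ...) {
  x$table[x$table$selected, ]
}

#' Tidy a depth ablation table
#'
#' @param x An `sfgcn_ablation`.
#' @param ... Unused.
#' @return Tibble with one metric-panel row per depth.
#' @method tidy sfgcn_ablation
#' @export
tidy.sfgcn_ablation <- function(x, ...) {
  x$table
}
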