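#' Confusion counts
#'
#' Tabulates true/false positives and negatives from binary labels and
#' hard predictions.
#'
#' @param labels Binary truth vector.
#' @param predictions Binary prediction vector of the same length.
#' @return One-row tibble with `TP`, `TN`, `FP`, `FN`, `n`.
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion_counts <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    abort("`labels` and `predictions` must have equal length.")
  }
  y <- check_binary_labels(labels)
  p <- check_binary_labels(predictions, "predictions")
  tibble(TP = sum(y == 1 & p == 1), TN = sum(y == 0 & p == 0),
         FP = sum(y == 0 & p == 1), FN = sum(y == 1 & p == 0),
         n = length(y))
}

#' Rank-based AUC (Mann-Whitney formula)
#'
#' `AUC = (sum of positive-score ranks - n_pos (n_pos + 1) / 2) /
#' (n_pos * n_neg)`, with tied scores receiving average ranks, which makes
#' the value equal to the proportion of correctly ordered positive/negative
#' pairs with ties counted one half.  With a single class the value is
#' undefined and 0.5 is returned with a warning.
#'
#' @param labels Binary truth vector.
#' @param scores Positive-class score vector.
#' @return A number in \[0, 1\].
#' @examples
#' rank_auc(c(1, 1, 0, 0), c(0.8, 0.3, 0.5, 0.1))  # 0.75
#' @export
rank_auc <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    abort("`labels` and `scores` must have equal length.")
  }
  y <- check_binary_labels(labels)
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    warn("AUC is undefined with a single class; returning 0.5.")
    return(0.5)
  }
  r <- rank(scores)  # average ranks for ties
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

ratio0 <- function(num, den, name) {
  if (den == 0) {
    warn(sprintf("%s has a zero denominator; returning 0.", name))
    return(0)
  }
  num / den
}

#' Compute the metric panel from confusion counts and scores
#'
#' Sensitivity `SN = TP / (TP + FN)`, specificity `SP = TN / (TN + FP)`,
#' accuracy `ACC = (TP + TN) / n`, precision `PRE = TP / (TP + FP)`,
#' `F1 = 2 PRE SN / (PRE + SN)`, Matthews correlation
#' `MCC = (TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, and the
#' rank-formula AUC from the raw scores.  Ratios with a zero denominator
#' return 0 with a warning; AUC with a single class returns 0.5 with a
#' warning.  All values are proportions; multiply by 100 where a
#' percentage presentation is wanted.
#'
#' @param counts One-row tibble from [confusion_counts()].
#' @param scores Positive-class scores (for AUC); `NULL` skips AUC
#'   (`NA`).
#' @param labels Binary truth vector matching `scores`.
#' @return One-row tibble: `SN`, `SP`, `ACC`, `PRE`, `F1`, `MCC`, `AUC`,
#'   `n`.
#' @export
compute_metrics <- function(counts, scores = NULL, labels = NULL) {
  stopifnot(all(c("TP", "TN", "FP", "FN") %in% names(counts)))
  TP <- as.numeric(counts$TP); TN <- as.numeric(counts$TN)
  FP <- as.numeric(counts$FP); FN <- as.numeric(counts$FN)
  n <- TP + TN + FP + FN
  sn <- ratio0(TP, TP + FN, "SN")
  sp <- ratio0(TN, TN + FP, "SP")
  acc <- ratio0(TP + TN, n, "ACC")
  pre <- ratio0(TP, TP + FP, "PRE")
  f1 <- if (pre + sn == 0) {
    warn("F1 has a zero denominator; returning 0.")
    0
  } else {
    2 * pre * sn / (pre + sn)
  }
  mcc_den <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  mcc <- if (mcc_den == 0) {
    warn("MCC has a zero denominator; returning 0.")
    0
  } else {
    (TP * TN - FP * FN) / mcc_den
  }
  auc <- if (is.null(scores)) NA_real_ else rank_auc(labels, scores)
  tibble(SN = sn, SP = sp, ACC = acc, PRE = pre, F1 = f1, MCC = mcc,
         AUC = auc, n = as.integer(n))
}

#' Metric panel straight from labels and scores
#'
#' Convenience wrapper: hard labels are `score > 0.5` (ties to the
#' negative class), then [confusion_counts()] and [compute_metrics()].
#'
#' @param labels Binary truth vector.
#' @param scores Positive-class scores.
#' @return One-row metric tibble (see [compute_metrics()]).
#' @export
metric_panel <- function(labels, scores) {
  preds <- as.integer(scores > 0.5)
  compute_metrics(confusion_counts(labels, preds), scores, labels)
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Builds stratified folds, trains a model on each fold's training part
#' and evaluates it on the held-out part, reporting per-fold metric
#' panels and their arithmetic mean.  Deterministic given the seeds in
#' the configurations and `seed` (fold assignment).
#'
#' @param data Labeled sequence tibble.
#' @param encoder,model,training Configurations passed to [sfgcn_fit()].
#' @param n_folds Number of folds; the study protocol uses 10.
#' @param seed Fold-assignment seed.
#' @return Object of class `sfgcn_cv`: list with `folds` (tibble, one row
#'   per fold) and `mean` (one-row tibble of column means).
#' @export
cross_validate <- function(data, encoder = encoder_config(),
                           model = model_config(),
                           training = train_config(),
                           n_folds = 10, seed = 1) {
  folds <- make_folds(data, n_folds = n_folds, seed = seed)
  rows <- lapply(folds, function(f) {
    fit <- sfgcn_fit(f$train, encoder = encoder, model = model,
                     training = training)
    pr <- predict(fit, f$heldout)
    panel <- metric_panel(f$heldout$label, pr$score)
    dplyr::bind_cols(tibble(fold = f$fold), panel)
  })
  fold_tbl <- bind_rows(rows)
  mean_tbl <- fold_tbl |>
    summarise(dplyr::across(c("SN", "SP", "ACC", "PRE", "F1", "MCC", "AUC"),
                            mean),
              n = sum(.data$n))
  structure(list(folds = fold_tbl, mean = mean_tbl,
                 n_folds = n_folds, encoder = encoder),
            class = "sfgcn_cv")
}

#' @export
print.sfgcn_cv <- function(x, ...) {
  cat(sprintf("<sfgcn_cv> %d folds (k = %d, d = %d)\n", x$n_folds,
              x$encoder$k, x$encoder$d))
  cat("mean panel:\n")
  print(x$mean)
  invisible(x)
}

#' Cross-validated (k, d) encoder grid experiment
#'
#' Cross-validates the pipeline for each (k, d) pair of the grid (default:
#' the four pairs k in \{2, 3\} x d in \{2, 3\}) and ranks the pairs by
#' mean held-out accuracy, breaking ties by higher AUC and then smaller
#' k and d.  The top-ranked pair is marked selected.
#'
#' @param data Labeled sequence tibble.
#' @param grid Data frame with columns `k`, `d`.
#' @param model,training Configurations passed to [cross_validate()].
#' @param n_folds,seed Cross-validation layout.
#' @return Object of class `sfgcn_grid`: list with `table` (ranked tibble
#'   with `k`, `d`, mean metrics, `selected`) and `selected`
#'   (`list(k, d)`).
#' @export
grid_experiment <- function(data,
                            grid = tidyr::expand_grid(k = c(2, 3), d = c(2, 3)),
                            model = model_config(),
                            training = train_config(),
                            n_folds = 10, seed = 1) {
  if (nrow(grid) == 0) abort("`grid` must contain at least one (k, d) pair.")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    enc <- encoder_config(k = grid$k[i], d = grid$d[i])
    cv <- cross_validate(data, encoder = enc, model = model,
                         training = training, n_folds = n_folds, seed = seed)
    dplyr::bind_cols(tibble(k = grid$k[i], d = grid$d[i]), cv$mean)
  })
  tab <- bind_rows(rows) |>
    arrange(desc(.data$ACC), desc(.data$AUC), .data$k, .data$d) |>
    mutate(rank = row_number(), selected = row_number() == 1L)
  structure(list(table = tab,
                 selected = list(k = tab$k[1], d = tab$d[1])),
            class = "sfgcn_grid")
}

#' @export
print.sfgcn_grid <- function(x, ...) {
  cat(sprintf("<sfgcn_grid> selected k = %d, d = %d\n",
              x$selected$k, x$selected$d))
  print(x$table)
  invisible(x)
}

#' Graph-convolution depth ablation
#'
#' Cross-validates the pipeline at each graph-convolution depth (default
#' 1 through 5) with the standard narrow-wide-narrow hidden profile, and
#' returns one mean metric panel per depth for inspection.  No automatic
#' selection is performed.
#'
#' @param data Labeled sequence tibble.
#' @param depths Integer vector of depths, each in 1..8.
#' @param encoder,model,training Configurations; `model`'s depth and
#'   hidden dims are overridden per run.
#' @param n_folds,seed Cross-validation layout.
#' @return Object of class `sfgcn_ablation`: list with `table` (tibble,
#'   one row per depth).
#' @export
depth_ablation <- function(data, depths = 1:5,
                           encoder = encoder_config(),
                           model = model_config(),
                           training = train_config(),
                           n_folds = 10, seed = 1) {
  if (any(depths < 1 | depths > 8)) abort("`depths` must lie in 1..8.")
  rows <- lapply(depths, function(depth) {
    mcfg <- model_config(
      n_gcn_layers = depth,
      gcn_hidden_dims = default_gcn_dims(depth),
      conv_channels = model$conv_channels,
      conv_kernel_size = model$conv_kernel_size,
      fc_hidden_dim = model$fc_hidden_dim,
      use_edge_weights = model$use_edge_weights,
      seed = model$seed)
    cv <- cross_validate(data, encoder = encoder, model = mcfg,
                         training = training, n_folds = n_folds, seed = seed)
    dplyr::bind_cols(tibble(depth = depth), cv$mean)
  })
  structure(list(table = bind_rows(rows)), class = "sfgcn_ablation")
}

#' @export
print.sfgcn_ablation <- function(x, ...) {
  cat("<sfgcn_ablation>\n")
  print(x$table)
  invisible(x)
}
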