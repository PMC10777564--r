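RUN_FORMAT_VERSION <- "sfgcn-run-1"

write_manifest <- function(out_dir, command, config) {
  manifest <- list(format = RUN_FORMAT_VERSION,
                   package_version = as.character(packageVersion("sfgcn")),
                   command = command,
                   config = config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

prepare_out_dir <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  invisible(out_dir)
}

load_run_dataset <- function(fasta = NULL, labels = NULL,
                             positive = NULL, negative = NULL) {
  if (!is.null(positive) && !is.null(negative)) {
    return(read_fasta_pair(positive, negative))
  }
  if (!is.null(fasta) && !is.null(labels)) {
    return(attach_labels(read_fasta(fasta), read_labels(labels)))
  }
  abort(paste0("Supply either `positive` + `negative` FASTA paths or ",
               "`fasta` + `labels`."))
}

#' Encode a FASTA file into serialized sequence feature graphs
#'
#' Writes one node table and one edge table per record (plain TSV, keyed
#' by sequence id in batch files `nodes.tsv` / `edges.tsv`), plus a
#' summary log and a run manifest.
#'
#' @param fasta Input FASTA path.
#' @param k,d Encoder parameters.
#' @param out_dir Output directory (created).
#' @return Invisibly, the summary tibble (record count, mean window
#'   count).
#' @export
run_encode <- function(fasta, k = 3, d = 3, out_dir) {
  prepare_out_dir(out_dir)
  data <- read_fasta(fasta)
  config <- encoder_config(k = k, d = d)
  graphs <- encode_dataset(data, config)
  nodes <- bind_rows(lapply(names(graphs), function(id) {
    g <- graphs[[id]]
    keep <- g$node_features > 0
    tibble(id = id, kmer = g$kmer_labels[keep],
           feature = g$node_features[keep])
  }))
  edges <- bind_rows(lapply(names(graphs), function(id) {
    g <- graphs[[id]]
    tibble(id = id,
           node_a = g$kmer_labels[g$edges$from],
           node_b = g$kmer_labels[g$edges$to],
           weight = g$edges$weight)
  }))
  readr::write_tsv(nodes, file.path(out_dir, "nodes.tsv"))
  readr::write_tsv(edges, file.path(out_dir, "edges.tsv"))
  summary_tbl <- tibble(
    n_records = length(graphs),
    mean_n_windows = mean(vapply(graphs, `[[`, numeric(1), "n_windows")),
    n_edges = nrow(edges))
  readr::write_tsv(summary_tbl, file.path(out_dir, "summary.tsv"))
  write_manifest(out_dir, "encode",
                 list(fasta = fasta, k = k, d = d))
  invisible(summary_tbl)
}

#' Generate and write a synthetic dataset
#'
#' Writes `sequences.fasta`, `labels.tsv` and a manifest.  Generator
#' parameters are embedded in the FASTA via a companion
#' `generator.json` echo for audit.
#'
#' @param cfg A [generator_config()].
#' @param out_dir Output directory.
#' @return Invisibly, the generated tibble.
#' @export
run_simulate <- function(cfg = generator_config(), out_dir) {
  prepare_out_dir(out_dir)
  ds <- generate_dataset(cfg)
  write_fasta(ds, file.path(out_dir, "sequences.fasta"))
  write_labels(ds, file.path(out_dir, "labels.tsv"))
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "generator.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(out_dir, "simulate", unclass(cfg))
  invisible(ds)
}

params_to_json_list <- function(params) {
  list(
    gcn = lapply(params$gcn, function(W) list(dim = dim(W), data = as.numeric(W))),
    conv = lapply(params$conv, function(l) {
      list(w_dim = dim(l$w), w = as.numeric(l$w), b = l$b)
    }),
    W1 = list(dim = dim(params$W1), data = as.numeric(params$W1)),
    b1 = params$b1,
    W2 = list(dim = dim(params$W2), data = as.numeric(params$W2)),
    b2 = params$b2,
    meta = attr(params, "meta")
  )
}

json_list_to_params <- function(x) {
  p <- list(
    gcn = lapply(x$gcn, function(W) matrix(W$data, W$dim[1], W$dim[2])),
    conv = lapply(x$conv, function(l) {
      list(w = matrix(l$w, l$w_dim[1], l$w_dim[2]), b = as.numeric(l$b))
    }),
    W1 = matrix(x$W1$data, x$W1$dim[1], x$W1$dim[2]),
    b1 = as.numeric(x$b1),
    W2 = matrix(x$W2$data, x$W2$dim[1], x$W2$dim[2]),
    b2 = as.numeric(x$b2)
  )
  structure(p, class = "sfgcn_params", meta = x$meta)
}

#' Write / read a self-describing model checkpoint
#'
#' JSON checkpoint holding a format version string, the encoder, model
#' and training configuration echoes, and every parameter tensor at full
#' precision.
#'
#' @param fit An `sfgcn_fit`.
#' @param path Checkpoint file path (`.json`).
#' @return `write_checkpoint()`: invisibly, `path`;
#'   `read_checkpoint()`: an `sfgcn_fit`-equivalent list usable by
#'   [predict.sfgcn_fit()].
#' @export
write_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "sfgcn_fit"))
  payload <- list(
    format = "sfgcn-checkpoint-1",
    encoder = unclass(fit$encoder),
    model = unclass(fit$model),
    training = unclass(fit$training),
    class_weights = fit$class_weights,
    params = params_to_json_list(fit$params)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!identical(x$format, "sfgcn-checkpoint-1")) {
    abort("Unrecognized checkpoint format.")
  }
  enc <- do.call(encoder_config, x$encoder[c("k", "d", "count_mode",
                                             "node_universe")])
  mcfg <- do.call(model_config, x$model[c("n_gcn_layers", "gcn_hidden_dims",
                                          "conv_channels", "conv_kernel_size",
                                          "fc_hidden_dim", "use_edge_weights",
                                          "seed")])
  tr <- x$training
  tcfg <- train_config(tr$learning_rate, tr$epochs, tr$batch_size,
                       tr$class_weights, tr$early_stopping_patience, tr$seed)
  structure(
    list(params = json_list_to_params(x$params), encoder = enc,
         model = mcfg, training = tcfg,
         class_weights = as.numeric(x$class_weights),
         log = tibble(), n_train = NA_integer_),
    class = "sfgcn_fit"
  )
}

#' Train a model from FASTA input and write its artifacts
#'
#' Splits the labeled input 8:1:1 (stratified), trains on the training
#' part with the validation part monitored, and writes the checkpoint,
#' the per-epoch training log, test-set predictions and metrics, the
#' split id lists and a manifest.
#'
#' @param fasta,labels One-FASTA + TSV labeling.
#' @param positive,negative Two-FASTA labeling (one file per class).
#' @param encoder,model,training Configurations.
#' @param split_seed Seed of the 8:1:1 split.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the fit and the test metric panel.
#' @export
run_train <- function(fasta = NULL, labels = NULL, positive = NULL,
                      negative = NULL, encoder = encoder_config(),
                      model = model_config(), training = train_config(),
                      split_seed = 1, out_dir) {
  prepare_out_dir(out_dir)
  ds <- load_run_dataset(fasta, labels, positive, negative)
  sp <- split_dataset(ds, seed = split_seed)
  fit <- sfgcn_fit(sp$train, validation = sp$validation,
                   encoder = encoder, model = model, training = training)
  write_checkpoint(fit, file.path(out_dir, "checkpoint.json"))
  readr::write_tsv(tidy(fit), file.path(out_dir, "training_log.tsv"))
  write_id_lists(sp, out_dir)
  pr <- predict(fit, sp$test)
  readr::write_tsv(pr, file.path(out_dir, "test_predictions.tsv"))
  panel <- metric_panel(sp$test$label, pr$score)
  readr::write_tsv(panel, file.path(out_dir, "test_metrics.tsv"))
  write_manifest(out_dir, "train",
                 list(encoder = unclass(encoder), model = unclass(model),
                      training = unclass(training), split_seed = split_seed))
  invisible(list(fit = fit, test_metrics = panel))
}

#' Score a FASTA file with a saved checkpoint
#'
#' @param checkpoint Checkpoint path from [run_train()].
#' @param fasta Sequences to score.
#' @param labels Optional TSV label table; when given, a metric panel is
#'   also written.
#' @param out_dir Output directory.
#' @return Invisibly, the prediction tibble.
#' @export
run_evaluate <- function(checkpoint, fasta, labels = NULL, out_dir) {
  prepare_out_dir(out_dir)
  fit <- read_checkpoint(checkpoint)
  ds <- read_fasta(fasta)
  if (!is.null(labels)) ds <- attach_labels(ds, read_labels(labels))
  pr <- predict(fit, ds)
  readr::write_tsv(pr, file.path(out_dir, "predictions.tsv"))
  if (!is.null(labels)) {
    panel <- metric_panel(ds$label, pr$score)
    readr::write_tsv(panel, file.path(out_dir, "metrics.tsv"))
  }
  write_manifest(out_dir, "evaluate",
                 list(checkpoint = checkpoint, fasta = fasta,
                      labels = labels))
  invisible(pr)
}

#' Cross-validate from FASTA input and write the fold table
#'
#' @inheritParams run_train
#' @param n_folds,seed Fold layout.
#' @return Invisibly, the `sfgcn_cv` object.
#' @export
run_crossval <- function(fasta = NULL, labels = NULL, positive = NULL,
                         negative = NULL, encoder = encoder_config(),
                         model = model_config(), training = train_config(),
                         n_folds = 10, seed = 1, out_dir) {
  prepare_out_dir(out_dir)
  ds <- load_run_dataset(fasta, labels, positive, negative)
  cv <- cross_validate(ds, encoder = encoder, model = model,
                       training = training, n_folds = n_folds, seed = seed)
  out <- bind_rows(
    tidy(cv) |> mutate(fold = as.character(.data$fold)),
    glance(cv) |> mutate(fold = "mean"))
  readr::write_tsv(out, file.path(out_dir, "cv_metrics.tsv"))
  write_manifest(out_dir, "crossval",
                 list(encoder = unclass(encoder), n_folds = n_folds,
                      seed = seed))
  invisible(cv)
}

#' Run the (k, d) grid experiment and write the ranked table
#'
#' @inheritParams run_crossval
#' @param grid Data frame of (k, d) pairs.
#' @return Invisibly, the `sfgcn_grid` object.
#' @export
run_grid <- function(fasta = NULL, labels = NULL, positive = NULL,
                     negative = NULL,
                     grid = tidyr::expand_grid(k = c(2, 3), d = c(2, 3)),
                     model = model_config(), training = train_config(),
                     n_folds = 10, seed = 1, out_dir) {
  prepare_out_dir(out_dir)
  ds <- load_run_dataset(fasta, labels, positive, negative)
  gx <- grid_experiment(ds, grid = grid, model = model, training = training,
                        n_folds = n_folds, seed = seed)
  readr::write_tsv(tidy(gx), file.path(out_dir, "grid_metrics.tsv"))
  write_manifest(out_dir, "grid",
                 list(grid = as.data.frame(grid), n_folds = n_folds,
                      seed = seed))
  invisible(gx)
}

#' Run the depth ablation and write its table
#'
#' @inheritParams run_crossval
#' @param depths Graph-convolution depths to sweep.
#' @return Invisibly, the `sfgcn_ablation` object.
#' @export
run_ablate <- function(fasta = NULL, labels = NULL, positive = NULL,
                       negative = NULL, depths = 1:5,
                       encoder = encoder_config(), model = model_config(),
                       training = train_config(), n_folds = 10, seed = 1,
                       out_dir) {
  prepare_out_dir(out_dir)
  ds <- load_run_dataset(fasta, labels, positive, negative)
  ab <- depth_ablation(ds, depths = depths, encoder = encoder, model = model,
                       training = training, n_folds = n_folds, seed = seed)
  readr::write_tsv(tidy(ab), file.path(out_dir, "ablation_metrics.tsv"))
  write_manifest(out_dir, "ablate",
                 list(depths = depths, encoder = unclass(encoder),
                      n_folds = n_folds, seed = seed))
  invisible(ab)
}
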