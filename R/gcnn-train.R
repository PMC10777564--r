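#' Model architecture configuration
#'
#' Architecture of the classifier: a stack of graph convolution layers
#' (default four, the depth at which the ablation panel peaks), three
#' one-dimensional convolutional layers, and a two-layer fully connected
#' softmax head.  Hidden sizes are modest by default, suited to the
#' `4^k`-node graphs the encoder emits.
#'
#' @param n_gcn_layers Number of graph convolution layers (>= 1).
#' @param gcn_hidden_dims Integer vector of per-layer output dimensions;
#'   length must equal `n_gcn_layers`.
#' @param conv_channels Output channels of the three 1-D convolutions.
#' @param conv_kernel_size Odd kernel width (zero padding preserves
#'   length).
#' @param fc_hidden_dim Width of the first fully connected layer.
#' @param use_edge_weights Consume the encoder's edge co-occurrence
#'   weights in the aggregation (default); `FALSE` gives the literal
#'   unweighted form.
#' @param seed Seed for parameter initialization.
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_gcn_layers = 4,
                         gcn_hidden_dims = default_gcn_dims(n_gcn_layers),
                         conv_channels = c(16, 32, 16),
                         conv_kernel_size = 3,
                         fc_hidden_dim = 64,
                         use_edge_weights = TRUE,
                         seed = 1) {
  if (n_gcn_layers < 1 || n_gcn_layers != floor(n_gcn_layers)) {
    abort("`n_gcn_layers` must be an integer >= 1.")
  }
  if (length(gcn_hidden_dims) != n_gcn_layers) {
    abort("`gcn_hidden_dims` must have one entry per graph convolution layer.")
  }
  if (length(conv_channels) != 3) abort("`conv_channels` must have length 3.")
  if (conv_kernel_size < 1 || conv_kernel_size %% 2 == 0) {
    abort("`conv_kernel_size` must be odd.")
  }
  structure(
    list(n_gcn_layers = as.integer(n_gcn_layers),
         gcn_hidden_dims = as.integer(gcn_hidden_dims),
         conv_channels = as.integer(conv_channels),
         conv_kernel_size = as.integer(conv_kernel_size),
         fc_hidden_dim = as.integer(fc_hidden_dim),
         use_edge_weights = isTRUE(use_edge_weights),
         seed = as.integer(seed)),
    class = "model_config"
  )
}

#' Default per-layer hidden dimensions for a given depth
#'
#' Narrow-wide-narrow profile: 16 at the ends, 32 in between; a single
#' layer gets 16.  Used by [model_config()] and the depth ablation.
#'
#' @param depth Number of graph convolution layers.
#' @return Integer vector of length `depth`.
#' @export
default_gcn_dims <- function(depth) {
  if (depth == 1) return(16L)
  as.integer(c(16, rep(32, depth - 2), 16))
}

#' Training configuration
#'
#' Plain mini-batch stochastic gradient descent on class-weighted
#' cross-entropy.  `class_weights = "balanced"` computes inverse
#' class-frequency weights `N / (2 * N_c)` on the training data, the
#' sample class-weighting strategy that keeps sensitivity from collapsing
#' on imbalanced sets; `"none"` disables weighting; a numeric pair sets
#' `c(w_negative, w_positive)` explicitly.
#'
#' @param learning_rate Positive step size (default 0.1, at which the
#'   loss descends cleanly on O(1)-scaled node features).
#' @param epochs Number of passes over the training data (>= 0; 0 returns
#'   the initial parameters).
#' @param batch_size Mini-batch size.
#' @param class_weights `"balanced"`, `"none"`, or a numeric pair.
#' @param early_stopping_patience Optional integer: stop when validation
#'   loss has not improved for this many epochs and restore the best
#'   parameters.  `NULL` (default) trains for exactly `epochs`.
#' @param seed Seed for mini-batch shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.1, epochs = 100, batch_size = 32,
                         class_weights = "balanced",
                         early_stopping_patience = NULL, seed = 1) {
  if (learning_rate <= 0) abort("`learning_rate` must be positive.")
  if (epochs < 0 || epochs != floor(epochs)) {
    abort("`epochs` must be a non-negative integer.")
  }
  if (batch_size < 1) abort("`batch_size` must be >= 1.")
  if (is.character(class_weights)) {
    class_weights <- match.arg(class_weights, c("balanced", "none"))
  } else if (!(is.numeric(class_weights) && length(class_weights) == 2 &&
               all(class_weights > 0))) {
    abort("`class_weights` must be \"balanced\", \"none\", or a positive pair.")
  }
  structure(
    list(learning_rate = learning_rate, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), class_weights = class_weights,
         early_stopping_patience = early_stopping_patience,
         seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Initialize model parameters
#'
#' All weight matrices are drawn from a symmetric uniform distribution
#' scaled by the inverse square root of their fan-in; biases start at
#' zero.  Deterministic given `model$seed`.
#'
#' @param encoder An [encoder_config()] (must use the full node universe).
#' @param model A [model_config()].
#' @return An object of class `sfgcn_params`: `gcn` (list of weight
#'   matrices), `conv` (list of `list(w, b)`), `W1`, `b1`, `W2`, `b2`.
#' @export
init_params <- function(encoder, model) {
  stopifnot(inherits(encoder, "encoder_config"), inherits(model, "model_config"))
  if (encoder$node_universe != "full") {
    abort("The model requires `node_universe = \"full\"` graphs.")
  }
  set.seed(model$seed)
  fan_unif <- function(nr, nc) {
    a <- 1 / sqrt(nr)
    matrix(runif(nr * nc, -a, a), nr, nc)
  }
  n_nodes <- 4L^encoder$k
  dims <- c(1L, model$gcn_hidden_dims)
  gcn <- lapply(seq_len(model$n_gcn_layers),
                function(l) fan_unif(dims[l], dims[l + 1]))
  m <- model$conv_kernel_size
  ch <- c(dims[length(dims)], model$conv_channels)
  conv <- lapply(1:3, function(t) {
    list(w = fan_unif(m * ch[t], ch[t + 1]), b = numeric(ch[t + 1]))
  })
  x_len <- n_nodes * ch[4]
  params <- list(
    gcn = gcn,
    conv = conv,
    # W1/W2 are stored (out x in), so the fan-in is the column count
    W1 = fan_unif2(model$fc_hidden_dim, x_len),
    b1 = numeric(model$fc_hidden_dim),
    W2 = fan_unif(model$fc_hidden_dim, 2),
    b2 = numeric(2)
  )
  structure(params, class = "sfgcn_params",
            meta = list(k = encoder$k, n_nodes = n_nodes,
                        kernel_size = m, channels = ch,
                        gcn_dims = dims, fc_hidden_dim = model$fc_hidden_dim))
}

# uniform +/- 1/sqrt(fan_in) for a (out x in) matrix
fan_unif2 <- function(nout, nin) {
  a <- 1 / sqrt(nin)
  matrix(runif(nout * nin, -a, a), nout, nin)
}

#' Number of trainable parameters
#' @param params An `sfgcn_params` object.
#' @return Integer count.
#' @export
n_params <- function(params) {
  length(params_to_vector(params))
}

params_to_vector <- function(p) {
  c(unlist(p$gcn, use.names = FALSE),
    unlist(lapply(p$conv, function(l) c(l$w, l$b)), use.names = FALSE),
    as.numeric(p$W1), p$b1, as.numeric(p$W2), p$b2)
}

vector_to_params <- function(v, template) {
  out <- template
  pos <- 0L
  take <- function(n) {
    res <- v[(pos + 1L):(pos + n)]
    pos <<- pos + n
    res
  }
  for (l in seq_along(out$gcn)) {
    W <- out$gcn[[l]]
    out$gcn[[l]] <- matrix(take(length(W)), nrow(W), ncol(W))
  }
  for (t in seq_along(out$conv)) {
    w <- out$conv[[t]]$w
    out$conv[[t]]$w <- matrix(take(length(w)), nrow(w), ncol(w))
    out$conv[[t]]$b <- take(length(out$conv[[t]]$b))
  }
  out$W1 <- matrix(take(length(out$W1)), nrow(out$W1), ncol(out$W1))
  out$b1 <- take(length(out$b1))
  out$W2 <- matrix(take(length(out$W2)), nrow(out$W2), ncol(out$W2))
  out$b2 <- take(length(out$b2))
  out
}

# Per-record fixed quantities reused across epochs: the normalized
# adjacency, the input node features, and the label.
precompute_caches <- function(data, encoder, use_edge_weights,
                              need_labels = TRUE) {
  check_dataset(data, need_labels = need_labels)
  graphs <- suppressWarnings(encode_dataset(data, encoder))
  lapply(seq_along(graphs), function(i) {
    g <- graphs[[i]]
    # the model consumes frequencies in units of the uniform expectation
    # (x 4^k), so input activations are O(1) at every k
    list(id = data$id[i],
         Ahat = normalized_adjacency(g, use_edge_weights),
         H0 = matrix(g$node_features * length(g$kmer_labels), ncol = 1),
         y = if (need_labels) as.integer(data$label[i]) else NA_integer_)
  })
}

# Full forward pass for one record.  With keep = TRUE all intermediates
# needed by the backward pass are returned.
forward_sample <- function(cache, params, pidx, keep = FALSE) {
  H <- cache$H0
  L <- length(params$gcn)
  gcnM <- gcnZ <- if (keep) vector("list", L)
  for (l in seq_len(L)) {
    M <- cache$Ahat %*% H
    Z <- M %*% params$gcn[[l]]
    H <- pmax(Z, 0)
    if (keep) {
      gcnM[[l]] <- M
      gcnZ[[l]] <- Z
    }
  }
  X <- H  # readout: rows are already in canonical k-mer order
  convXcol <- convZ <- if (keep) vector("list", 3)
  for (t in 1:3) {
    Xcol <- conv_im2col(X, pidx)
    Z <- sweep(Xcol %*% params$conv[[t]]$w, 2, params$conv[[t]]$b, `+`)
    X <- pmax(Z, 0)
    if (keep) {
      convXcol[[t]] <- Xcol
      convZ[[t]] <- Z
    }
  }
  x <- as.numeric(X)
  a1 <- drop(params$W1 %*% x) + params$b1
  h1 <- pmax(a1, 0)
  logits <- drop(crossprod(params$W2, h1)) + params$b2
  prob <- softmax(logits)
  if (!keep) return(list(prob = prob))
  list(prob = prob, gcnM = gcnM, gcnZ = gcnZ,
       convXcol = convXcol, convZ = convZ, x = x, a1 = a1, h1 = h1)
}

# Backward pass for one record given d(loss)/d(logits); returns the
# gradient as a flat vector in params_to_vector() layout.
backward_sample <- function(fw, cache, params, dlogits, pidx) {
  g <- params  # reuse shapes; every slot is overwritten below
  g$b2 <- dlogits
  g$W2 <- outer(fw$h1, dlogits)
  dh1 <- drop(params$W2 %*% dlogits)
  da1 <- dh1 * (fw$a1 > 0)
  g$b1 <- da1
  g$W1 <- outer(da1, fw$x)
  n_nodes <- nrow(cache$H0)
  dX <- matrix(drop(crossprod(params$W1, da1)), n_nodes)
  m <- ncol(pidx)
  for (t in 3:1) {
    dZ <- dX * (fw$convZ[[t]] > 0)
    g$conv[[t]]$b <- colSums(dZ)
    g$conv[[t]]$w <- crossprod(fw$convXcol[[t]], dZ)
    dXcol <- dZ %*% t(params$conv[[t]]$w)
    C_in <- ncol(dXcol) / m
    dXprev <- matrix(0, n_nodes, C_in)
    for (u in seq_len(m)) {
      idx <- pidx[, u]
      valid <- idx > 1L
      rows <- idx[valid] - 1L
      dXprev[rows, ] <- dXprev[rows, ] +
        dXcol[valid, ((u - 1L) * C_in + 1L):(u * C_in), drop = FALSE]
    }
    dX <- dXprev
  }
  dH <- dX
  for (l in length(params$gcn):1) {
    dZ <- dH * (fw$gcnZ[[l]] > 0)
    g$gcn[[l]] <- crossprod(fw$gcnM[[l]], dZ)
    if (l > 1) dH <- cache$Ahat %*% tcrossprod(dZ, params$gcn[[l]])
  }
  params_to_vector(g)
}

resolve_class_weights <- function(spec, labels) {
  if (is.numeric(spec)) return(spec)
  if (identical(spec, "none")) return(c(1, 1))
  n <- length(labels)
  n1 <- sum(labels == 1)
  n0 <- n - n1
  c(n / (2 * n0), n / (2 * n1))
}

# weighted mean loss and scores over a cache list (no gradients)
evaluate_caches <- function(caches, params, pidx, class_weights) {
  scores <- vapply(caches, function(cc) {
    forward_sample(cc, params, pidx)$prob[2]
  }, numeric(1))
  y <- vapply(caches, `[[`, integer(1), "y")
  loss <- cross_entropy_loss(y, scores, class_weights)
  list(scores = scores, labels = y, loss = loss,
       acc = mean((scores > 0.5) == (y == 1)))
}

#' Fit the sequence-feature-graph classifier
#'
#' Encodes every training sequence as a feature graph, initializes
#' parameters from `model$seed`, and runs mini-batch gradient descent on
#' class-weighted cross-entropy for `training$epochs` epochs.  The
#' per-epoch log records the mean weighted training loss over the epoch's
#' mini-batches and, when a validation set is supplied, validation loss
#' and accuracy.  Identical seeds and data give identical trajectories.
#'
#' @param data Labeled training tibble (`id`, `sequence`, `label`); both
#'   classes must be present.
#' @param validation Optional labeled tibble monitored each epoch (and
#'   used for early stopping when
#'   `training$early_stopping_patience` is set).
#' @param encoder An [encoder_config()].
#' @param model A [model_config()].
#' @param training A [train_config()].
#' @return An object of class `sfgcn_fit` with elements `params`,
#'   `encoder`, `model`, `training`, `class_weights`, `log` (tibble with
#'   `epoch`, `train_loss`, `val_loss`, `val_acc`), `n_train`.
#' @examples
#' \donttest{
#' ds <- generate_dataset(generator_config(n_per_class = 15, length = 60))
#' fit <- sfgcn_fit(ds, encoder = encoder_config(k = 2, d = 2),
#'                  model = model_config(n_gcn_layers = 1,
#'                                       gcn_hidden_dims = 4,
#'                                       conv_channels = c(4, 4, 4),
#'                                       fc_hidden_dim = 8),
#'                  training = train_config(epochs = 3))
#' glance(fit)
#' }
#' @export
sfgcn_fit <- function(data, validation = NULL,
                      encoder = encoder_config(),
                      model = model_config(),
                      training = train_config()) {
  check_dataset(data)
  if (length(unique(data$label)) < 2) {
    abort("Training data must contain both classes.")
  }
  caches <- precompute_caches(data, encoder, model$use_edge_weights)
  val_caches <- if (!is.null(validation)) {
    precompute_caches(validation, encoder, model$use_edge_weights)
  }
  params <- init_params(encoder, model)
  cw <- resolve_class_weights(training$class_weights, data$label)
  pidx <- conv_pad_index(4L^encoder$k, model$conv_kernel_size)
  n <- length(caches)
  theta <- params_to_vector(params)
  log_rows <- vector("list", training$epochs)
  best <- list(loss = Inf, theta = theta, epoch = 0L)
  patience <- training$early_stopping_patience
  set.seed(training$seed)
  for (epoch in seq_len(training$epochs)) {
    perm <- sample.int(n)
    batches <- split(perm, ceiling(seq_along(perm) / training$batch_size))
    epoch_loss <- 0
    for (batch in batches) {
      gvec <- numeric(length(theta))
      batch_loss <- 0
      for (i in batch) {
        cc <- caches[[i]]
        fw <- forward_sample(cc, params, pidx, keep = TRUE)
        wgt <- cw[cc$y + 1L]
        batch_loss <- batch_loss - wgt * log(max(fw$prob[cc$y + 1L], 1e-12))
        onehot <- c(1 - cc$y, cc$y)
        gvec <- gvec + backward_sample(fw, cc, params, wgt * (fw$prob - onehot),
                                       pidx)
      }
      if (!is.finite(batch_loss)) {
        abort(sprintf(
          "Non-finite loss in epoch %d; lower the learning rate.", epoch))
      }
      theta <- theta - training$learning_rate * (gvec / length(batch))
      params <- vector_to_params(theta, params)
      epoch_loss <- epoch_loss + batch_loss
    }
    val_loss <- val_acc <- NA_real_
    if (!is.null(val_caches)) {
      ev <- evaluate_caches(val_caches, params, pidx, cw)
      val_loss <- ev$loss
      val_acc <- ev$acc
      if (ev$loss < best$loss - 1e-12) {
        best <- list(loss = ev$loss, theta = theta, epoch = epoch)
      }
    }
    log_rows[[epoch]] <- tibble(epoch = epoch, train_loss = epoch_loss / n,
                                val_loss = val_loss, val_acc = val_acc)
    if (!is.null(patience) && !is.null(val_caches) &&
        epoch - best$epoch >= patience) {
      log_rows <- log_rows[seq_len(epoch)]
      theta <- best$theta
      params <- vector_to_params(theta, params)
      break
    }
  }
  structure(
    list(params = params, encoder = encoder, model = model,
         training = training, class_weights = cw,
         log = bind_rows(log_rows), n_train = n),
    class = "sfgcn_fit"
  )
}

#' @export
print.sfgcn_fit <- function(x, ...) {
  cat(sprintf(
    "<sfgcn_fit> k = %d, d = %d | %d GCN layer(s) | %s parameters | %d epoch(s)\n",
    x$encoder$k, x$encoder$d, x$model$n_gcn_layers,
    format(n_params(x$params), big.mark = ","), nrow(x$log)))
  if (nrow(x$log) > 0) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("  final train loss %.4f", last$train_loss))
    if (!is.na(last$val_loss)) {
      cat(sprintf(" | val loss %.4f | val ACC %.3f", last$val_loss,
                  last$val_acc))
    }
    cat("\n")
  }
  invisible(x)
}

#' Predict essentiality scores for new sequences
#'
#' Runs the fitted model over each record and returns the positive-class
#' softmax score and the hard label (`score > 0.5`; the 0.5 tie goes to
#' the negative class).  Predictions are per-record, so record order does
#' not affect them.
#'
#' @param object An `sfgcn_fit`.
#' @param data Tibble with `id`, `sequence` (a `label` column, if present,
#'   is carried through).
#' @param ... Unused.
#' @return Tibble with `id`, (`label`,) `score`, `pred`.
#' @export
predict.sfgcn_fit <- function(object, data, ...) {
  check_dataset(data, need_labels = FALSE)
  caches <- precompute_caches(data, object$encoder,
                              object$model$use_edge_weights,
                              need_labels = FALSE)
  pidx <- conv_pad_index(4L^object$encoder$k, object$model$conv_kernel_size)
  scores <- vapply(caches, function(cc) {
    forward_sample(cc, object$params, pidx)$prob[2]
  }, numeric(1))
  out <- tibble(id = data$id)
  if ("label" %in% names(data)) out$label <- as.integer(data$label)
  out$score <- scores
  out$pred <- as.integer(scores > 0.5)
  out
}

# loss of a whole batch as a function of the flat parameter vector;
# the independent quantity differentiated by the finite-difference check
batch_loss_at <- function(theta, template, caches, pidx, class_weights) {
  params <- vector_to_params(theta, template)
  ev <- evaluate_caches(caches, params, pidx, class_weights)
  ev$loss
}

# analytic gradient of the same batch loss (mean over samples)
batch_grad_at <- function(theta, template, caches, pidx, class_weights) {
  params <- vector_to_params(theta, template)
  gvec <- numeric(length(theta))
  for (cc in caches) {
    fw <- forward_sample(cc, params, pidx, keep = TRUE)
    wgt <- class_weights[cc$y + 1L]
    onehot <- c(1 - cc$y, cc$y)
    gvec <- gvec + backward_sample(fw, cc, params, wgt * (fw$prob - onehot),
                                   pidx)
  }
  gvec / length(caches)
}
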