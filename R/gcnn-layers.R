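#' Rectified linear unit
#'
#' Elementwise `max(0, x)`, the nonlinearity used after every graph
#' convolution, 1-D convolution and the first fully connected layer.
#'
#' @param x Numeric vector, matrix or array.
#' @return Object of the same shape.
#' @examples
#' relu(c(-2, 0, 3))
#' @export
relu <- function(x) {
  pmax(x, 0)
}

#' One graph convolution layer
#'
#' Aggregates neighbor features with symmetric degree normalization and
#' applies a linear map and ReLU:
#' `Z_i = sum_(j in N(i)) a_ij / sqrt(d_i d_j) * h_j * W`, `H_i = ReLU(Z_i)`.
#' In the literal formulation `a_ij = 1` for every present edge and `d` is
#' the plain degree; in weighted mode (the default) `a_ij` is the edge
#' co-occurrence weight and `d` the weighted degree, so the encoder's edge
#' features are consumed by the model.  No self term is added: a node
#' contributes to itself only through an explicit self-loop edge.  Isolated
#' nodes output zero rows.
#'
#' @param H Node representation matrix (nodes x features).
#' @param graph The `sfg` object supplying adjacency.
#' @param W Weight matrix (in-features x out-features).
#' @param use_edge_weights Weighted (default) or literal unweighted
#'   aggregation.
#' @return Matrix of new node representations (nodes x out-features).
#' @export
graph_convolution_layer <- function(H, graph, W, use_edge_weights = TRUE) {
  H <- as.matrix(H)
  W <- as.matrix(W)
  if (nrow(H) != length(graph$kmer_labels)) {
    abort("`H` must have one row per graph node.")
  }
  if (ncol(H) != nrow(W)) abort("`W` input dimension must match `H` features.")
  Ahat <- normalized_adjacency(graph, use_edge_weights)
  relu(Ahat %*% H %*% W)
}

#' Read node representations out as a fixed-shape tensor
#'
#' Arranges the final node representations in canonical lexicographic
#' k-mer order as a 1-D signal of length `4^k` whose channels are the final
#' hidden dimension, the interface between the graph convolutions and the
#' 1-D convolutional stack.  Requires the full node universe so every
#' sequence yields an identically shaped tensor; storage order of the
#' input rows is irrelevant.
#'
#' @param H Node representation matrix with rownames or paired `labels`.
#' @param labels Character vector naming `H`'s rows (k-mer per row).
#' @param canonical_order Target row order (defaults to the sorted k-mer
#'   universe inferred from `labels`).
#' @return Matrix `length(canonical_order)` x `ncol(H)`.
#' @export
readout_to_tensor <- function(H, labels, canonical_order = NULL) {
  H <- as.matrix(H)
  if (length(labels) != nrow(H)) abort("One label per row of `H` is required.")
  k <- nchar(labels[1])
  canonical_order <- canonical_order %||% kmer_universe(k)
  if (length(labels) != length(canonical_order) ||
      !setequal(labels, canonical_order)) {
    abort(paste0(
      "Readout requires the full 4^k node universe; ",
      "observed-universe graphs have variable node sets and are rejected."))
  }
  H[match(canonical_order, labels), , drop = FALSE]
}

# zero-padded gather indices for a same-length 1-D convolution:
# entry [i, u] is the padded-row index of input position i + u - r - 1
# (1 points at the zero pad row)
conv_pad_index <- function(n, kernel_size) {
  r <- (kernel_size - 1L) %/% 2L
  pos <- outer(seq_len(n), seq_len(kernel_size) - 1L - r, `+`)
  idx <- pos + 1L
  idx[pos < 1L | pos > n] <- 1L
  idx
}

# im2col: signal (n x C) -> (n x kernel_size*C); column (u-1)*C + c holds
# channel c at offset u
conv_im2col <- function(X, pidx) {
  Xpad <- rbind(0, X)
  m <- ncol(pidx)
  C <- ncol(X)
  out <- matrix(0, nrow(X), m * C)
  for (u in seq_len(m)) {
    out[, ((u - 1L) * C + 1L):(u * C)] <- Xpad[pidx[, u], , drop = FALSE]
  }
  out
}

#' Three-layer 1-D convolutional stack
#'
#' Applies three sequential one-dimensional convolutions (stride 1, zero
#' padding preserving the signal length, ReLU after each) to the readout
#' tensor and flattens the result column-major into a feature vector for
#' the fully connected head.
#'
#' @param x Input signal: matrix (positions x channels).
#' @param kernels List of 3 layers, each `list(w, b)` with `w` a
#'   `(kernel_size * in_channels) x out_channels` matrix in offset-major
#'   row layout (rows `(u-1)*C + c` hold channel c at kernel offset u) and
#'   `b` a length-`out_channels` bias.
#' @return Numeric vector of length `nrow(x) * out_channels_3`.
#' @export
conv_stack <- function(x, kernels) {
  x <- as.matrix(x)
  if (length(kernels) != 3) abort("`kernels` must hold exactly 3 layers.")
  for (layer in kernels) {
    C_in <- ncol(x)
    m <- nrow(layer$w) / C_in
    if (m != floor(m)) abort("Kernel rows must be a multiple of input channels.")
    pidx <- conv_pad_index(nrow(x), as.integer(m))
    z <- conv_im2col(x, pidx) %*% layer$w
    z <- sweep(z, 2, layer$b, `+`)
    x <- relu(z)
  }
  as.numeric(x)
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Fully connected softmax head
#'
#' `y_hat = softmax(ReLU(W1 x + b1) W2 + b2)`: two fully connected layers
#' mapping the flattened convolutional features to a two-class probability
#' pair (negative, positive).  Components are positive and sum to 1.
#'
#' @param x Flattened feature vector.
#' @param params List (or `sfgcn_params`) with `W1` (hidden x length(x)),
#'   `b1`, `W2` (hidden x 2), `b2`.
#' @return Numeric probability pair `c(p_negative, p_positive)`.
#' @export
head_forward <- function(x, params) {
  if (ncol(params$W1) != length(x)) abort("`W1` width must match length(x).")
  h <- relu(drop(params$W1 %*% x) + params$b1)
  logits <- drop(crossprod(params$W2, h)) + params$b2
  softmax(logits)
}

#' Class-weighted binary cross-entropy loss
#'
#' `L = (1/N) * sum_n w_(y_n) * -(y_n log p_n + (1 - y_n) log(1 - p_n))`,
#' with probabilities clipped to `[1e-12, 1 - 1e-12]`.  `class_weights`
#' is an optional `c(w_negative, w_positive)` pair; balanced classes with
#' inverse-frequency weights recover the unweighted loss.
#'
#' @param labels Binary vector.
#' @param probs Positive-class probabilities, same length.
#' @param class_weights Optional numeric pair; `NULL` = unweighted.
#' @return Non-negative scalar.
#' @examples
#' cross_entropy_loss(c(1, 0), c(0.5, 0.5))  # log(2)
#' @export
cross_entropy_loss <- function(labels, probs, class_weights = NULL) {
  if (length(labels) != length(probs)) {
    abort("`labels` and `probs` must have equal length.")
  }
  y <- check_binary_labels(labels)
  eps <- 1e-12
  p <- pmin(pmax(probs, eps), 1 - eps)
  w <- if (is.null(class_weights)) rep(1, length(y)) else {
    if (length(class_weights) != 2) abort("`class_weights` must be a pair.")
    class_weights[y + 1L]
  }
  mean(-w * (y * log(p) + (1 - y) * log(1 - p)))
}
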