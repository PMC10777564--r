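# Independent brute-force oracles and tiny fixture builders used across the
# suite.  Oracles are deliberately naive (per-character loops, dense matrix
# algebra, quadratic pair counting) and share no code with the package
# internals they check.

random_dna <- function(L, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

# every (offset, junction) tuple enumerated one character at a time
oracle_gapped_kmers <- function(bases, k, d) {
  ch <- strsplit(toupper(bases), "")[[1]]
  L <- length(ch)
  span <- k + d - 1
  out <- character(0)
  for (j in seq_len(k - 1)) {
    s <- 1
    while (s + span - 1 <= L) {
      pos <- c(seq(s, s + j - 1), seq(s + j - 1 + d, s + span - 1))
      w <- paste(ch[pos], collapse = "")
      if (!grepl("[^ACGT]", w)) out <- c(out, w)
      s <- s + 1
    }
  }
  out
}

# dense symmetric-normalization oracle for one graph convolution layer
oracle_gcn_layer <- function(graph, H, W, use_edge_weights) {
  n <- length(graph$kmer_labels)
  A <- matrix(0, n, n)
  e <- graph$edges
  for (r in seq_len(nrow(e))) {
    w <- if (use_edge_weights) e$weight[r] else 1
    i <- e$from[r]; j <- e$to[r]
    A[i, j] <- A[i, j] + w
    if (i != j) A[j, i] <- A[j, i] + w
  }
  deg <- rowSums(A)
  Dinv <- diag(ifelse(deg > 0, 1 / sqrt(deg), 0), n)
  pmax(Dinv %*% A %*% Dinv %*% H %*% W, 0)
}

# a random sfg-shaped graph (arbitrary node labels, random weighted edges)
random_sfg <- function(n_nodes, n_edges, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pairs <- unique(data.frame(
    from = sample.int(n_nodes, n_edges, replace = TRUE),
    to = sample.int(n_nodes, n_edges, replace = TRUE)))
  swap <- pairs$from > pairs$to
  tmp <- pairs$from[swap]; pairs$from[swap] <- pairs$to[swap]; pairs$to[swap] <- tmp
  pairs <- unique(pairs)
  structure(
    list(kmer_labels = sprintf("node%03d", seq_len(n_nodes)),
         node_features = runif(n_nodes),
         edges = tibble::tibble(from = pairs$from, to = pairs$to,
                                weight = sample(1:5, nrow(pairs), replace = TRUE)),
         n_windows = NA_integer_,
         config = NULL),
    class = "sfg")
}

# naive sliding-window 1-D convolution stack (zero padding, stride 1, ReLU)
oracle_conv_stack <- function(x, kernels) {
  for (layer in kernels) {
    n <- nrow(x); C_in <- ncol(x)
    m <- nrow(layer$w) / C_in
    r <- (m - 1) / 2
    out <- matrix(0, n, ncol(layer$w))
    for (i in seq_len(n)) {
      for (o in seq_len(ncol(layer$w))) {
        acc <- layer$b[o]
        for (u in seq_len(m)) {
          p <- i + u - 1 - r
          if (p >= 1 && p <= n) {
            for (cc in seq_len(C_in)) {
              acc <- acc + x[p, cc] * layer$w[(u - 1) * C_in + cc, o]
            }
          }
        }
        out[i, o] <- acc
      }
    }
    x <- pmax(out, 0)
  }
  as.numeric(x)
}

# proportion of correctly ordered positive/negative score pairs, ties = 1/2
oracle_pair_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# small labeled dataset with arbitrary sequences
toy_dataset <- function(n_per_class = 10, length = 40, seed = 1) {
  generate_dataset(generator_config(n_per_class = n_per_class,
                                    length = length, seed = seed))
}

# a micro model configuration that keeps unit tests fast
micro_model <- function(n_gcn_layers = 1, seed = 11) {
  model_config(n_gcn_layers = n_gcn_layers,
               gcn_hidden_dims = rep(4, n_gcn_layers),
               conv_channels = c(3, 3, 3), conv_kernel_size = 3,
               fc_hidden_dim = 8, seed = seed)
}
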