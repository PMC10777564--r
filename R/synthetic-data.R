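#' Synthetic two-class sequence generator configuration
#'
#' Defines a pair of Markov sequence models whose classes differ only in
#' statistics of order `order + 1` and above.  The class-0 model is a
#' uniform order-`order` chain; the class-1 model mixes that shared base
#' model with a seeded doubly-stochastic perturbation (per-context-group
#' permutation rows) at weight `signal_strength`.  The construction keeps
#' the stationary distribution over `order`-grams uniform for both
#' classes, so with the default `order = 2` the classes have identical
#' expected mono- and dinucleotide composition but different trinucleotide
#' composition -- a planted signal that a k = 3 encoder can see and a
#' k = 2 encoder cannot.
#'
#' @param n_per_class Sequences per class (class 1; class 0 scaled by
#'   `class_imbalance`).
#' @param length Sequence length in bases (>= 10).
#' @param order Markov order (default 2).
#' @param signal_strength Mixing weight s in \[0, 1\] of the class-1
#'   perturbation; 0 makes the classes identical.
#' @param class_imbalance Optional ratio of negatives to positives
#'   (`NULL` = balanced).
#' @param seed Integer seed; all generator randomness flows from it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_per_class = 200, length = 300, order = 2,
                             signal_strength = 0.8, class_imbalance = NULL,
                             seed = 1) {
  if (n_per_class < 1) abort("`n_per_class` must be >= 1.")
  if (length < 10) abort("`length` must be >= 10.")
  if (order < 1 || order > 4 || order != floor(order)) {
    abort("`order` must be an integer in 1..4.")
  }
  if (signal_strength < 0 || signal_strength > 1) {
    abort("`signal_strength` must lie in [0, 1].")
  }
  if (!is.null(class_imbalance) && class_imbalance <= 0) {
    abort("`class_imbalance` must be positive.")
  }
  structure(
    list(n_per_class = as.integer(n_per_class), length = as.integer(length),
         order = as.integer(order), signal_strength = signal_strength,
         class_imbalance = class_imbalance, seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Class-specific Markov transition models
#'
#' Builds the shared base model (uniform transitions from every
#' order-`order` context) and the class-1 model
#' `(1 - s) * base + s * perturbation`.  The perturbation assigns, within
#' every group of four contexts sharing their trailing `order - 1` bases, a
#' seeded permutation of deterministic next-base rows; each group's columns
#' then sum to 1, which keeps the uniform distribution over contexts
#' stationary for any s.  Rows are exact probability distributions by
#' construction.
#'
#' @param cfg A [generator_config()].
#' @return List of two `transition_model` objects (`class0`, `class1`),
#'   each with fields `order`, `contexts`, `initial`, `transitions` (one
#'   row per context, columns A, C, G, T).
#' @export
make_class_models <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  m <- cfg$order
  contexts <- kmer_universe(m)
  nc <- length(contexts)
  base <- matrix(1 / 4, nc, 4, dimnames = list(contexts, DNA_BASES))
  set.seed(cfg$seed)
  perturb <- matrix(0, nc, 4, dimnames = list(contexts, DNA_BASES))
  # groups of 4 contexts sharing the trailing (order - 1) bases; rows within
  # a group are indexed by the leading base
  suffix <- substring(contexts, 2, m)
  for (sfx in unique(suffix)) {
    rows <- which(suffix == sfx)
    perm <- sample.int(4)
    perturb[cbind(rows, perm)] <- 1
  }
  s <- cfg$signal_strength
  trans1 <- (1 - s) * base + s * perturb
  initial <- rep(1 / nc, nc)
  model <- function(tr) {
    structure(list(order = m, contexts = contexts, initial = initial,
                   transitions = tr),
              class = "transition_model")
  }
  list(class0 = model(base), class1 = model(trans1))
}

# vectorized sampling of n sequences of given length from one model;
# consumes the current RNG stream
sample_markov_sequences <- function(model, n, length) {
  m <- model$order
  nctx <- length(model$contexts)
  ctx <- sample.int(nctx, n, replace = TRUE, prob = model$initial)
  chars <- matrix("", n, length)
  # decode the initial context into the first m bases
  rem <- ctx - 1L
  for (pos in m:1) {
    chars[, pos] <- DNA_BASES[rem %% 4L + 1L]
    rem <- rem %/% 4L
  }
  cum <- t(apply(model$transitions, 1, cumsum))
  for (t in seq(m + 1, length)) {
    u <- runif(n)
    nxt <- rowSums(u > cum[ctx, , drop = FALSE]) + 1L
    chars[, t] <- DNA_BASES[nxt]
    ctx <- ((ctx - 1L) %% 4L^(m - 1)) * 4L + (nxt - 1L) + 1L
  }
  do.call(paste0, lapply(seq_len(length), function(t) chars[, t]))
}

#' Generate a labeled synthetic two-class dataset
#'
#' Samples `n_per_class` sequences from the class-1 model and
#' `round(n_per_class * class_imbalance)` (default: the same number) from
#' the class-0 model.  Fully deterministic given `cfg$seed`.
#'
#' @param cfg A [generator_config()].
#' @return Tibble with `id`, `sequence`, `label` (0/1).
#' @examples
#' ds <- generate_dataset(generator_config(n_per_class = 5, length = 40))
#' ds
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  models <- make_class_models(cfg)  # seeds the stream from cfg$seed
  n1 <- cfg$n_per_class
  n0 <- if (is.null(cfg$class_imbalance)) n1 else {
    max(1L, as.integer(round(n1 * cfg$class_imbalance)))
  }
  seq0 <- sample_markov_sequences(models$class0, n0, cfg$length)
  seq1 <- sample_markov_sequences(models$class1, n1, cfg$length)
  bind_rows(
    tibble(id = sprintf("neg_%04d", seq_len(n0)), sequence = seq0, label = 0L),
    tibble(id = sprintf("pos_%04d", seq_len(n1)), sequence = seq1, label = 1L)
  )
}

#' Empirical k-mer divergence between the two classes
#'
#' Total-variation distance between the pooled per-class relative k-mer
#' frequency vectors (contiguous k-mers, N-containing windows excluded).
#' A diagnostic for how much class signal an order-k encoder can see:
#' 0 for identical compositions, 1 for disjoint k-mer supports.
#'
#' @param data Labeled sequence tibble; both classes must be present.
#' @param k Word length.
#' @return A number in \[0, 1\].
#' @export
empirical_kmer_divergence <- function(data, k) {
  check_dataset(data)
  cfg <- encoder_config(k = k, d = 1, count_mode = "relative")
  class_freq <- function(cl) {
    seqs <- data$sequence[data$label == cl]
    if (length(seqs) == 0) abort(sprintf("Class %d is absent.", cl))
    windows <- unlist(lapply(seqs, extract_contiguous_kmers, k = k),
                      use.names = FALSE)
    count_node_frequencies(windows, cfg)
  }
  p <- class_freq(1)
  q <- class_freq(0)
  0.5 * sum(abs(p - q))
}
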