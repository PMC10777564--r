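#' Encoder configuration
#'
#' Parameters of the sequence-to-graph encoder.  `k` is the number of
#' informative bases per window; `d` is the positional distance between the
#' two informative bases flanking the gap in a gapped window, so `d - 1`
#' wildcard positions are skipped and `d = 1` means contiguous windows only
#' (the gapped pass is a no-op).  With `k = 3, d = 3` the gapped pattern with
#' the gap after the second base reads `GT**A`: informative bases G, T, A
#' with two skipped positions.
#'
#' @param k Window size in informative bases (1--8).
#' @param d Gap distance; `d = 1` disables gapped extraction.
#' @param count_mode `"relative"` (counts divided by the total number of
#'   valid counted windows, contiguous and gapped pooled) or `"raw"`.
#' @param node_universe `"full"` (all `4^k` k-mers, lexicographic, absent
#'   k-mers zero-featured) or `"observed"` (only k-mers seen in the
#'   sequence).  The model requires `"full"` so every graph shares one node
#'   order.
#' @return An object of class `encoder_config`.
#' @examples
#' encoder_config(k = 3, d = 3)
#' @export
encoder_config <- function(k = 3, d = 3,
                           count_mode = c("relative", "raw"),
                           node_universe = c("full", "observed")) {
  check_k(k)
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 1 || d != floor(d)) {
    abort("`d` must be a single integer >= 1.")
  }
  structure(
    list(k = as.integer(k), d = as.integer(d),
         count_mode = match.arg(count_mode),
         node_universe = match.arg(node_universe)),
    class = "encoder_config"
  )
}

#' @export
print.encoder_config <- function(x, ...) {
  cat(sprintf("<encoder_config> k = %d, d = %d, counts = %s, universe = %s\n",
              x$k, x$d, x$count_mode, x$node_universe))
  invisible(x)
}

#' Contiguous k-mer windows of a sequence
#'
#' Slides a window of length `k` one base at a time, yielding exactly
#' `max(0, L - k + 1)` windows in left-to-right order.  Windows containing
#' an ambiguous base (N) are kept as `NA` placeholders so the window count
#' is preserved; downstream counting skips them.
#'
#' @param bases DNA string (case-insensitive).
#' @param k Window size.
#' @return Character vector of windows, `NA` where a window overlaps an N.
#' @examples
#' extract_contiguous_kmers("GTACTA", 2)
#' @export
extract_contiguous_kmers <- function(bases, k) {
  check_k(k)
  bases <- toupper(bases)
  L <- nchar(bases)
  if (L < k) return(character(0))
  w <- substring(bases, 1:(L - k + 1), k:L)
  w[grepl("[^ACGT]", w)] <- NA_character_
  w
}

#' Gapped k-mer matches of a sequence
#'
#' For each internal junction j (1 <= j <= k - 1) and each start offset,
#' emits the k informative bases of a window in which positions up to the
#' junction are contiguous, the base after the junction sits `d` positions
#' after its predecessor (`d - 1` skipped wildcards), and the remaining
#' bases are contiguous.  Each match spans `k + d - 1` sequence positions.
#' The returned identity is the k informative bases only; the gap position
#' is not encoded in the label, so gapped matches pool onto ordinary k-mer
#' nodes.  Matches touching an N are dropped.  `d = 1` returns an empty
#' vector (contiguous windows are handled separately).
#'
#' @param bases DNA string (case-insensitive).
#' @param k Number of informative bases (>= 2).
#' @param d Gap distance (>= 1).
#' @return Character vector of k-mer identities, ordered by junction then
#'   offset.
#' @examples
#' extract_gapped_kmers("GTACTA", k = 3, d = 3)
#' @export
extract_gapped_kmers <- function(bases, k, d) {
  check_k(k)
  if (k < 2) abort("Gapped extraction needs `k` >= 2.")
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 1 || d != floor(d)) {
    abort("`d` must be a single integer >= 1.")
  }
  if (d == 1) return(character(0))
  bases <- toupper(bases)
  L <- nchar(bases)
  span <- k + d - 1
  if (L < span) return(character(0))
  n_off <- L - span + 1
  out <- vector("list", k - 1)
  for (j in seq_len(k - 1)) {
    s <- seq_len(n_off)
    left <- substring(bases, s, s + j - 1)
    right <- substring(bases, s + j + d - 1, s + span - 1)
    w <- paste0(left, right)
    out[[j]] <- w[!grepl("[^ACGT]", w)]
  }
  unlist(out, use.names = FALSE) %||% character(0)
}

#' Node occurrence frequencies over the k-mer universe
#'
#' Tabulates the pooled window list (contiguous plus gapped) onto the node
#' universe.  In `"relative"` mode counts are divided by the number of
#' valid (non-`NA`) windows, so features sum to 1 whenever any window was
#' counted.
#'
#' @param windows Character vector of k-mer windows; `NA` entries are
#'   skipped but still absent from the divisor.
#' @param config An [encoder_config()].
#' @return Named numeric vector, one entry per node.
#' @examples
#' count_node_frequencies(extract_contiguous_kmers("GTACTA", 2),
#'                        encoder_config(k = 2, d = 1))
#' @export
count_node_frequencies <- function(windows, config) {
  stopifnot(inherits(config, "encoder_config"))
  valid <- windows[!is.na(windows)]
  if (length(valid) > 0 && any(nchar(valid) != config$k)) {
    abort(sprintf("All windows must have length k = %d.", config$k))
  }
  labels <- if (config$node_universe == "full") {
    kmer_universe(config$k)
  } else {
    sort(unique(valid))
  }
  counts <- tabulate(factor(valid, levels = labels), nbins = length(labels))
  feat <- as.numeric(counts)
  if (config$count_mode == "relative" && length(valid) > 0) {
    feat <- feat / length(valid)
  }
  setNames(feat, labels)
}

#' Adjacency counts of consecutive windows
#'
#' Counts undirected co-occurrence edges between consecutive contiguous
#' windows: each valid pair (w_i, w_(i+1)) adds 1 to the edge between the
#' two k-mer identities (self-loops allowed when the two windows are
#' equal).  A pair is dropped when either window is invalid (`NA`).  The
#' accumulated weight therefore equals the number of valid consecutive
#' pairs.
#'
#' @param windows Ordered character vector of contiguous windows (may
#'   contain `NA`).
#' @return A tibble with columns `node_a`, `node_b` (k-mer strings,
#'   `node_a <= node_b`) and integer `weight`.
#' @examples
#' count_adjacency(extract_contiguous_kmers("GTACTA", 2))
#' @export
count_adjacency <- function(windows) {
  n <- length(windows)
  if (n < 2) {
    return(tibble(node_a = character(0), node_b = character(0),
                  weight = integer(0)))
  }
  a <- windows[-n]
  b <- windows[-1]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) == 0) {
    return(tibble(node_a = character(0), node_b = character(0),
                  weight = integer(0)))
  }
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  tibble(node_a = lo, node_b = hi) |>
    count(.data$node_a, .data$node_b, name = "weight") |>
    arrange(.data$node_a, .data$node_b)
}

#' Build the sequence feature graph of one sequence
#'
#' Encodes a DNA sequence as a graph G = (n, e): nodes are k-mers with
#' occurrence-frequency features pooled over contiguous and gapped windows;
#' edges connect k-mers that occur in consecutive contiguous windows, with
#' co-occurrence counts as weights.  `n_windows` records the contiguous
#' window count `max(0, L - k + 1)`.  Sequences shorter than the window
#' span produce an empty (all-zero, edgeless) graph.
#'
#' @param bases DNA string (case-insensitive; N allowed).
#' @param config An [encoder_config()].
#' @return An object of class `sfg`: a list with `kmer_labels`,
#'   `node_features`, `edges` (tibble `from`, `to`, `weight`; node indices,
#'   `from <= to`), `n_windows`, and the `config`.
#' @examples
#' g <- sequence_feature_graph("GTACTA", encoder_config(k = 2, d = 1))
#' g$edges
#' @export
sequence_feature_graph <- function(bases, config = encoder_config()) {
  stopifnot(inherits(config, "encoder_config"))
  contig <- extract_contiguous_kmers(bases, config$k)
  gapped <- if (config$d >= 2 && config$k >= 2) {
    extract_gapped_kmers(bases, config$k, config$d)
  } else {
    character(0)
  }
  pooled <- c(contig, gapped)
  feats <- count_node_frequencies(pooled, config)
  labels <- names(feats)
  edge_tbl <- count_adjacency(contig)
  edges <- tibble(
    from = match(edge_tbl$node_a, labels),
    to = match(edge_tbl$node_b, labels),
    weight = as.numeric(edge_tbl$weight)
  )
  structure(
    list(kmer_labels = labels,
         node_features = unname(feats),
         edges = edges,
         n_windows = length(contig),
         config = config),
    class = "sfg"
  )
}

#' @export
print.sfg <- function(x, ...) {
  cat(sprintf(
    "<sfg> %d nodes (k = %d, d = %d), %d edges, %d contiguous windows\n",
    length(x$kmer_labels), x$config$k, x$config$d, nrow(x$edges), x$n_windows))
  invisible(x)
}

#' Encode every sequence of a dataset
#'
#' @param data Tibble with `id` and `sequence` columns.
#' @param config An [encoder_config()].
#' @return Named list of [sequence_feature_graph()] objects, one per record,
#'   in dataset order.
#' @export
encode_dataset <- function(data, config = encoder_config()) {
  check_dataset(data, need_labels = FALSE)
  short <- nchar(data$sequence) < config$k + config$d - 1
  if (any(short)) {
    warn(sprintf(
      "%d sequence(s) shorter than k + d - 1 = %d produce empty graphs.",
      sum(short), config$k + config$d - 1))
  }
  setNames(lapply(data$sequence, sequence_feature_graph, config = config),
           data$id)
}

#' Symmetrically normalized adjacency matrix of a graph
#'
#' Dense matrix `D^(-1/2) A D^(-1/2)` used by the graph convolution.  In
#' weighted mode `A` holds the accumulated co-occurrence weights and `D`
#' the weighted degrees; in unweighted mode every present edge contributes
#' 1.  Rows of isolated nodes are zero.  A self-loop contributes its weight
#' once to the diagonal and once to the degree.
#'
#' @param graph An `sfg` object.
#' @param use_edge_weights Multiply neighbor contributions by edge weights
#'   (default) or treat all present edges as weight 1.
#' @return Dense numeric matrix, nodes in `graph$kmer_labels` order.
#' @export
normalized_adjacency <- function(graph, use_edge_weights = TRUE) {
  stopifnot(inherits(graph, "sfg"))
  n <- length(graph$kmer_labels)
  A <- matrix(0, n, n)
  e <- graph$edges
  if (nrow(e) > 0) {
    if (any(e$weight <= 0)) abort("Edge weights must be positive.")
    w <- if (use_edge_weights) e$weight else rep(1, nrow(e))
    A[cbind(e$from, e$to)] <- A[cbind(e$from, e$to)] + w
    off <- e$from != e$to
    if (any(off)) {
      A[cbind(e$to[off], e$from[off])] <-
        A[cbind(e$to[off], e$from[off])] + w[off]
    }
  }
  deg <- rowSums(A)
  s <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  A * outer(s, s)
}

#' Write a graph as plain-text node and edge tables
#'
#' Serializes one sequence feature graph to `<stem>_nodes.tsv` (kmer,
#' feature) and `<stem>_edges.tsv` (node_a, node_b, weight).
#'
#' @param graph An `sfg` object.
#' @param stem Output path stem.
#' @return Invisibly, the two file paths.
#' @export
write_sfg <- function(graph, stem) {
  stopifnot(inherits(graph, "sfg"))
  nodes_path <- paste0(stem, "_nodes.tsv")
  edges_path <- paste0(stem, "_edges.tsv")
  readr::write_tsv(
    tibble(kmer = graph$kmer_labels, feature = graph$node_features),
    nodes_path)
  readr::write_tsv(
    tibble(node_a = graph$kmer_labels[graph$edges$from],
           node_b = graph$kmer_labels[graph$edges$to],
           weight = graph$edges$weight),
    edges_path)
  invisible(c(nodes = nodes_path, edges = edges_path))
}

#' Render a gapped k-mer pattern
#'
#' Shows the wildcard form of a gapped window: the informative bases with
#' `d - 1` `*` placeholders after the junction.  With `k = 3, d = 3` and
#' the junction after the second base, `"GTA"` renders as `"GT**A"`.
#'
#' @param kmer The k informative bases.
#' @param d Gap distance (`d - 1` wildcards).
#' @param junction Number of informative bases before the gap
#'   (1 to `nchar(kmer) - 1`).
#' @return The pattern string.
#' @examples
#' gapped_pattern("GTA", d = 3, junction = 2)
#' @export
gapped_pattern <- function(kmer, d, junction) {
  k <- nchar(kmer)
  if (junction < 1 || junction >= k) {
    abort("`junction` must lie between 1 and k - 1.")
  }
  if (d < 2) abort("A gapped pattern needs `d` >= 2.")
  paste0(substr(kmer, 1, junction), strrep("*", d - 1),
         substr(kmer, junction + 1, k))
}
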