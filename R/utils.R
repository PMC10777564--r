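DNA_BASES <- c("A", "C", "G", "T")

#' Enumerate the k-mer universe
#'
#' All `4^k` DNA k-mers over \{A, C, G, T\} in lexicographic order.  This is
#' the canonical node order of every sequence feature graph built with
#' `node_universe = "full"`, and the order in which node representations are
#' read out into the downstream convolutional stack.
#'
#' @param k Word length (1--8).
#' @return Character vector of length `4^k`, lexicographically sorted.
#' @examples
#' kmer_universe(1)
#' head(kmer_universe(3))
#' @export
kmer_universe <- function(k) {
  check_k(k)
  if (k == 1) return(DNA_BASES)
  g <- expand.grid(rep(list(DNA_BASES), k), stringsAsFactors = FALSE)
  do.call(paste0, rev(g))
}

check_k <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k != floor(k)) {
    abort("`k` must be a single integer >= 1.")
  }
  if (k > 8) {
    abort("`k` must be <= 8 (the node universe grows as 4^k).")
  }
  invisible(as.integer(k))
}

check_binary_labels <- function(labels, arg = "labels") {
  if (anyNA(labels) || !all(labels %in% c(0, 1))) {
    abort(sprintf("`%s` must be binary (0 = non-essential, 1 = essential).", arg))
  }
  invisible(as.integer(labels))
}

# tibble(id, sequence, label) contract shared by every data-frame-first
# function in the package
check_dataset <- function(data, need_labels = TRUE) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  need <- c("id", "sequence", if (need_labels) "label")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("`data` is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(data$id)) {
    abort("Sequence ids must be unique within a dataset.")
  }
  if (any(!nzchar(data$id)) || anyNA(data$id)) abort("Sequence ids must be non-empty.")
  if (any(nchar(data$sequence) < 1) || anyNA(data$sequence)) {
    abort("Every sequence must have length >= 1.")
  }
  if (need_labels) check_binary_labels(data$label, "data$label")
  invisible(data)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
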