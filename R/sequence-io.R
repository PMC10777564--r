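#' Read a FASTA file into a labeled sequence tibble
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file.  Bases are
#' uppercased; IUPAC ambiguity codes other than N are collapsed to N with a
#' warning; record order is preserved; ids (header up to the first
#' whitespace) must be unique.
#'
#' @param path FASTA file path.
#' @param label Optional binary class label (1 = essential,
#'   0 = non-essential) attached to every record; `NA` when labels come
#'   from a separate table (see [read_labels()]).
#' @return A tibble with columns `id`, `sequence`, `label`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1", "gtacta"), fa)
#' read_fasta(fa, label = 1)
#' @export
read_fasta <- function(path, label = NULL) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0) abort(sprintf("FASTA file is empty: %s", path))
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate sequence id(s) in %s: %s", path,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- toupper(as.character(x))
  ambiguous <- grepl("[^ACGTN]", seqs)
  if (any(ambiguous)) {
    warn(sprintf(
      "%d record(s) contain IUPAC ambiguity codes other than N; mapped to N.",
      sum(ambiguous)))
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  lab <- if (is.null(label)) NA_integer_ else check_binary_labels(label, "label")
  tibble(id = unname(ids), sequence = unname(seqs), label = lab)
}

#' Read one FASTA file per class
#'
#' The common layout for essential-gene benchmarks: the positive subset
#' (essential genes) and negative subset in separate FASTA files.
#'
#' @param positive_path FASTA of essential genes (label 1).
#' @param negative_path FASTA of non-essential genes (label 0).
#' @return Combined tibble (`id`, `sequence`, `label`), positives first.
#' @export
read_fasta_pair <- function(positive_path, negative_path) {
  pos <- read_fasta(positive_path, label = 1)
  neg <- read_fasta(negative_path, label = 0)
  out <- bind_rows(pos, neg)
  check_dataset(out)
  out
}

#' Read a tab-separated label table
#'
#' @param path TSV with columns `id` and `label` (0/1).
#' @return Tibble with `id`, `label`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) abort(sprintf("Label table not found: %s", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), label = readr::col_integer()))
  check_binary_labels(tab$label, "label")
  if (anyDuplicated(tab$id)) abort("Duplicate ids in label table.")
  tibble(id = tab$id, label = tab$label)
}

#' Attach labels from a table to a sequence tibble
#'
#' @param data Tibble with `id`, `sequence`.
#' @param labels Tibble with `id`, `label` (e.g. from [read_labels()]).
#' @return `data` with its `label` column filled in.
#' @export
attach_labels <- function(data, labels) {
  check_dataset(data, need_labels = FALSE)
  missing_ids <- setdiff(data$id, labels$id)
  if (length(missing_ids) > 0) {
    abort(sprintf("No label for id(s): %s",
                  paste(head(missing_ids, 5), collapse = ", ")))
  }
  data$label <- labels$label[match(data$id, labels$id)]
  check_dataset(data)
  data
}

#' Write sequences to FASTA (and labels to TSV)
#'
#' @param data Tibble with `id`, `sequence` (and `label` for
#'   `write_labels()`).
#' @param path Output file path.
#' @param width Line-wrap width for FASTA output.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(data, path, width = 60) {
  check_dataset(data, need_labels = FALSE)
  x <- Biostrings::DNAStringSet(setNames(data$sequence, data$id))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_labels <- function(data, path) {
  check_dataset(data)
  readr::write_tsv(data[, c("id", "label")], path)
  invisible(path)
}

# largest-remainder allocation of n items over fractions
largest_remainder <- function(n, fractions) {
  q <- n * fractions
  base <- floor(q)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(q - base, seq_along(fractions), decreasing = c(TRUE, FALSE),
                 method = "radix")
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' Partitions a labeled dataset into train, validation and test subsets
#' (default ratio 8:1:1).  With `stratified = TRUE` each class is shuffled
#' and allocated separately with a largest-remainder rounding rule, so
#' per-class proportions match the requested fractions within one record.
#' Deterministic given `seed`.
#'
#' @param data Tibble with `id`, `sequence`, `label`.
#' @param train,validation,test Fractions in (0, 1) summing to 1.
#' @param stratified Stratify by class (default).  Stratified splitting
#'   requires at least 10 records per class.
#' @param seed Integer seed.
#' @return Named list of tibbles: `train`, `validation`, `test`.
#' @examples
#' ds <- generate_dataset(generator_config(n_per_class = 20, length = 50))
#' sp <- split_dataset(ds, seed = 1)
#' vapply(sp, nrow, integer(1))
#' @export
split_dataset <- function(data, train = 0.8, validation = 0.1, test = 0.1,
                          stratified = TRUE, seed = 1) {
  check_dataset(data)
  fr <- c(train = train, validation = validation, test = test)
  if (any(fr <= 0) || any(fr >= 1)) {
    abort("Each split fraction must lie strictly between 0 and 1.")
  }
  if (abs(sum(fr) - 1) > 1e-9) abort("Split fractions must sum to 1.")
  assign_group <- function(idx) {
    counts <- largest_remainder(length(idx), fr)
    rep(names(fr), counts)
  }
  set.seed(seed)
  grp <- character(nrow(data))
  if (stratified) {
    for (cl in c(0, 1)) {
      idx <- which(data$label == cl)
      if (length(idx) == 0) {
        abort(sprintf("Class %d is absent; cannot stratify.", cl))
      }
      if (length(idx) < 10) {
        abort("Stratified splitting needs >= 10 records per class.")
      }
      idx <- sample(idx)
      grp[idx] <- assign_group(idx)
    }
  } else {
    idx <- sample.int(nrow(data))
    grp[idx] <- assign_group(idx)
  }
  lapply(setNames(nm = names(fr)),
         function(g) data[grp == g, , drop = FALSE])
}

#' Stratified k-fold cross-validation folds
#'
#' Assigns each record to one of `n_folds` held-out folds, stratified by
#' class.  Extra records (when a class size is not a multiple of
#' `n_folds`) are rotated across folds so overall fold sizes differ by at
#' most one.  Deterministic given `seed`.
#'
#' @param data Tibble with `id`, `sequence`, `label`; each class must have
#'   at least `n_folds` records.
#' @param n_folds Number of folds (>= 2); the study protocol uses 10.
#' @param seed Integer seed.
#' @return List of length `n_folds`; element i is
#'   `list(fold = i, train = <tibble>, heldout = <tibble>)`.
#' @export
make_folds <- function(data, n_folds = 10, seed = 1) {
  check_dataset(data)
  if (!is.numeric(n_folds) || n_folds < 2 || n_folds != floor(n_folds)) {
    abort("`n_folds` must be an integer >= 2.")
  }
  set.seed(seed)
  fold <- integer(nrow(data))
  shift <- 0L
  for (cl in c(0, 1)) {
    idx <- which(data$label == cl)
    if (length(idx) < n_folds) {
      abort(sprintf("Class %d has %d record(s); need >= n_folds = %d.",
                    cl, length(idx), n_folds))
    }
    idx <- sample(idx)
    fold[idx] <- ((seq_along(idx) - 1L + shift) %% n_folds) + 1L
    shift <- (shift + length(idx)) %% n_folds
  }
  lapply(seq_len(n_folds), function(i) {
    list(fold = i,
         train = data[fold != i, , drop = FALSE],
         heldout = data[fold == i, , drop = FALSE])
  })
}

#' Write split/fold membership as plain-text id lists
#'
#' One id per line per subset file, for audit of a split or fold layout.
#'
#' @param splits Named list of tibbles (e.g. from [split_dataset()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_id_lists <- function(splits, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(splits), function(nm) {
    p <- file.path(dir, paste0(nm, "_ids.txt"))
    writeLines(splits[[nm]]$id, p)
    p
  }, character(1))
  invisible(paths)
}
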