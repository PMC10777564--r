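test_that("FASTA reading normalizes case, keeps order, validates ids", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1 some description", "gtacta", ">g2", "ACGT", "ACGT"), fa)
  ds <- read_fasta(fa, label = 1)
  expect_equal(ds$id, c("g1", "g2"))
  expect_equal(ds$sequence, c("GTACTA", "ACGTACGT"))
  expect_equal(ds$label, c(1L, 1L))

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1", "ACGT", ">g1", "TTTT"), dup)
  expect_error(read_fasta(dup), "Duplicate")

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty), "empty")
  expect_error(read_fasta(file.path(tempdir(), "nope.fasta")), "not found")
})

test_that("ambiguity codes other than N collapse to N with a warning", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1", "ACGRYSWN"), fa)
  expect_warning(ds <- read_fasta(fa), "ambiguity")
  expect_equal(ds$sequence, "ACGNNNNN")
})

test_that("FASTA + labels round-trips ids, bases and labels exactly", {
  ds <- toy_dataset(n_per_class = 12, length = 35, seed = 3)
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_fasta(ds, fa, width = 20)  # wrapped lines on purpose
  write_labels(ds, tsv)
  back <- attach_labels(read_fasta(fa), read_labels(tsv))
  expect_equal(back$id, ds$id)
  expect_equal(back$sequence, ds$sequence)
  expect_equal(back$label, ds$label)
})

test_that("two-FASTA labeling assigns one class per file", {
  ds <- toy_dataset(n_per_class = 5, length = 30, seed = 4)
  pos <- withr::local_tempfile(fileext = ".fasta")
  neg <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(ds[ds$label == 1, ], pos)
  write_fasta(ds[ds$label == 0, ], neg)
  both <- read_fasta_pair(pos, neg)
  expect_equal(sum(both$label == 1), 5)
  expect_equal(sum(both$label == 0), 5)
})

test_that("stratified 8:1:1 split is exact under divisibility", {
  ds <- toy_dataset(n_per_class = 50, length = 30, seed = 5)
  sp <- split_dataset(ds, seed = 9)
  expect_equal(vapply(sp, nrow, integer(1)),
               c(train = 80L, validation = 10L, test = 10L))
  for (part in sp) {
    expect_equal(sum(part$label == 1), nrow(part) / 2)
  }
  # partition: disjoint and covering
  all_ids <- sort(unlist(lapply(sp, `[[`, "id"), use.names = FALSE))
  expect_equal(all_ids, sort(ds$id))
})

test_that("splitting is deterministic given the seed", {
  ds <- toy_dataset(n_per_class = 17, length = 30, seed = 6)
  a <- split_dataset(ds, seed = 42)
  b <- split_dataset(ds, seed = 42)
  expect_identical(a, b)
  c <- split_dataset(ds, seed = 43)
  expect_false(identical(a$train$id, c$train$id))
})

test_that("largest-remainder allocation keeps 10+10 within one record of 8:1:1", {
  # hand enumeration: 10 * (0.8, 0.1, 0.1) = (8, 1, 1) exactly per class
  ds <- toy_dataset(n_per_class = 10, length = 30, seed = 7)
  sp <- split_dataset(ds, seed = 1)
  for (cl in 0:1) {
    per_class <- vapply(sp, function(p) sum(p$label == cl), integer(1))
    expect_equal(unname(per_class), c(8L, 1L, 1L))
  }
})

test_that("split rejects bad fractions, missing classes, tiny classes", {
  ds <- toy_dataset(n_per_class = 12, length = 30, seed = 8)
  expect_error(split_dataset(ds, train = 0.7, validation = 0.2, test = 0.2),
               "sum to 1")
  expect_error(split_dataset(ds, train = 1, validation = 0.0, test = 0.0),
               "between 0 and 1")
  ds1 <- ds[ds$label == 1, ]
  expect_error(split_dataset(ds1), "absent")
  small <- dplyr::bind_rows(ds[ds$label == 1, ][1:3, ], ds[ds$label == 0, ])
  expect_error(split_dataset(small), ">= 10")
})

test_that("stratified folds partition the data with balanced sizes", {
  ds <- toy_dataset(n_per_class = 10, length = 30, seed = 9)
  folds <- make_folds(ds, n_folds = 10, seed = 2)
  expect_length(folds, 10)
  for (f in folds) {
    expect_equal(sum(f$heldout$label == 1), 1)
    expect_equal(sum(f$heldout$label == 0), 1)
    expect_equal(sort(c(f$train$id, f$heldout$id)), sort(ds$id))
  }
  held <- unlist(lapply(folds, function(f) f$heldout$id), use.names = FALSE)
  expect_equal(sort(held), sort(ds$id))  # disjoint cover
})

test_that("fold sizes differ by at most one even without divisibility", {
  # 23 records: 13 positives + 10 negatives
  ds <- toy_dataset(n_per_class = 13, length = 30, seed = 10)
  ds <- ds[-(1:3), ]  # drop 3 negatives -> 10 neg, 13 pos
  folds <- make_folds(ds, n_folds = 10, seed = 3)
  sizes <- vapply(folds, function(f) nrow(f$heldout), integer(1))
  expect_equal(sum(sizes), 23L)
  expect_lte(max(sizes) - min(sizes), 1L)
})

test_that("splits and folds stay stratified on randomized dataset sizes", {
  set.seed(1234)
  for (rep in 1:8) {
    n1 <- sample(10:100, 1)
    n0 <- sample(10:100, 1)
    ds <- generate_dataset(generator_config(
      n_per_class = n1, length = 30, class_imbalance = n0 / n1,
      seed = 1000 + rep))
    sp <- split_dataset(ds, seed = rep)
    expect_equal(sort(unlist(lapply(sp, `[[`, "id"), use.names = FALSE)), sort(ds$id))
    parent_ratio <- mean(ds$label == 1)
    for (part in sp) {
      expect_lte(abs(mean(part$label == 1) - parent_ratio), 1 / nrow(part) + 1e-12)
    }
    folds <- make_folds(ds, n_folds = 5, seed = rep)
    held <- unlist(lapply(folds, function(f) f$heldout$id), use.names = FALSE)
    expect_equal(sort(held), sort(ds$id))
    expect_equal(anyDuplicated(held), 0L)
  }
})

test_that("folds require enough records per class", {
  ds <- toy_dataset(n_per_class = 4, length = 30, seed = 11)
  expect_error(make_folds(ds, n_folds = 5), "need >= n_folds")
})

test_that("id lists are written one per subset", {
  ds <- toy_dataset(n_per_class = 10, length = 30, seed = 12)
  sp <- split_dataset(ds, seed = 1)
  dir <- withr::local_tempdir()
  paths <- write_id_lists(sp, dir)
  expect_true(all(file.exists(paths)))
  expect_equal(readLines(file.path(dir, "train_ids.txt")), sp$train$id)
})
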