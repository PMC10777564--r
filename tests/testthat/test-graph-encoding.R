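test_that("contiguous windows follow the L - k + 1 sliding rule", {
  expect_equal(extract_contiguous_kmers("GTACTA", 1),
               c("G", "T", "A", "C", "T", "A"))
  expect_equal(extract_contiguous_kmers("GTACTA", 2),
               c("GT", "TA", "AC", "CT", "TA"))
  expect_equal(extract_contiguous_kmers("GTACTA", 3),
               c("GTA", "TAC", "ACT", "CTA"))
  expect_equal(extract_contiguous_kmers("GTACTA", 4),
               c("GTAC", "TACT", "ACTA"))
  expect_equal(extract_contiguous_kmers("GTACTA", 5),
               c("GTACT", "TACTA"))
  expect_equal(extract_contiguous_kmers("GTACTA", 6), "GTACTA")
  expect_equal(extract_contiguous_kmers("A", 2), character(0))
  expect_equal(extract_contiguous_kmers("gtacta", 2),
               extract_contiguous_kmers("GTACTA", 2))
  expect_error(extract_contiguous_kmers("ACGT", 0), "integer >= 1")
})

test_that("window count equals L - k + 1 over random sequences", {
  set.seed(21)
  for (rep in 1:20) {
    L <- sample(1:10000, 1)
    s <- random_dna(L)
    for (k in 1:6) {
      expect_length(extract_contiguous_kmers(s, k), max(0, L - k + 1))
    }
  }
})

test_that("windows overlapping an N become invalid placeholders", {
  w <- extract_contiguous_kmers("ACNGT", 2)
  expect_equal(w, c("AC", NA, NA, "GT"))
})

test_that("gapped windows skip d - 1 positions after each junction", {
  # k = 3, d = 3 on GTACTA: junction 1 -> (1,4,5) GCT, (2,5,6) TTA;
  # junction 2 -> (1,2,5) GTT, (2,3,6) TAA (1-based informative positions)
  expect_setequal(extract_gapped_kmers("GTACTA", 3, 3),
                  c("GCT", "TTA", "GTT", "TAA"))
  expect_equal(gapped_pattern("GTA", d = 3, junction = 2), "GT**A")
  expect_equal(gapped_pattern("GTA", d = 2, junction = 1), "G*TA")
  expect_equal(extract_gapped_kmers("GTACTA", 3, 1), character(0))
  expect_equal(extract_gapped_kmers("ACG", 3, 4), character(0))  # span > L
  expect_error(extract_gapped_kmers("ACGT", 1, 3), "k")
})

test_that("gapped match count per junction is L - (k + d - 1) + 1", {
  set.seed(22)
  for (rep in 1:10) {
    L <- sample(20:300, 1)
    s <- random_dna(L)
    k <- sample(2:4, 1)
    d <- sample(2:4, 1)
    expect_length(extract_gapped_kmers(s, k, d),
                  (k - 1) * max(0, L - (k + d - 1) + 1))
  }
})

test_that("gapped enumeration matches the naive quadratic oracle", {
  set.seed(23)
  for (rep in 1:60) {
    k <- sample(2:4, 1)
    d <- sample(2:5, 1)
    L <- sample(k + d:60, 1)
    s <- random_dna(L, alphabet = c("A", "C", "G", "T", "N"))
    expect_equal(sort(extract_gapped_kmers(s, k, d)),
                 sort(oracle_gapped_kmers(s, k, d)))
  }
})

test_that("node frequencies are relative to the valid window total", {
  cfg <- encoder_config(k = 2, d = 1)
  f <- count_node_frequencies(extract_contiguous_kmers("GTACTA", 2), cfg)
  expect_length(f, 16)
  expect_equal(unname(f["TA"]), 0.4)
  expect_equal(unname(f[c("GT", "AC", "CT")]), rep(0.2, 3))
  expect_equal(sum(f), 1)
  expect_equal(sum(f > 0), 4)

  expect_equal(unname(count_node_frequencies(character(0), cfg)), rep(0, 16))
  raw <- encoder_config(k = 3, d = 1, count_mode = "raw")
  f3 <- count_node_frequencies("AAA", raw)
  expect_equal(unname(f3["AAA"]), 1)
  expect_equal(sum(f3), 1)
  expect_error(count_node_frequencies(c("AA", "AAA"), raw), "length k")
})

test_that("adjacency counts consecutive valid pairs with self-loops", {
  e <- count_adjacency(c("GT", "TA", "AC", "CT", "TA"))
  expect_equal(nrow(e), 4)
  expect_equal(e$weight, rep(1L, 4))
  expect_setequal(paste(e$node_a, e$node_b),
                  c("GT TA", "AC TA", "AC CT", "CT TA"))

  loop <- count_adjacency(extract_contiguous_kmers("AAAA", 3))
  expect_equal(loop, tibble::tibble(node_a = "AAA", node_b = "AAA",
                                    weight = 1L))
  expect_equal(nrow(count_adjacency("GTA")), 0)
  expect_equal(nrow(count_adjacency(c("AC", NA, "GT"))), 0)
})

test_that("the full graph composes counts, edges and window totals", {
  g <- sequence_feature_graph("GTACTA", encoder_config(k = 2, d = 1))
  expect_s3_class(g, "sfg")
  expect_length(g$kmer_labels, 16)
  expect_equal(g$kmer_labels, kmer_universe(2))
  expect_equal(sum(g$node_features > 0), 4)
  expect_equal(g$node_features[match("TA", g$kmer_labels)], 0.4)
  expect_equal(nrow(g$edges), 4)
  expect_equal(g$edges$weight, rep(1, 4))
  expect_equal(g$n_windows, 5)
})

test_that("sequences shorter than the span give empty graphs", {
  g <- sequence_feature_graph("AC", encoder_config(k = 3, d = 3))
  expect_length(g$kmer_labels, 64)
  expect_equal(sum(g$node_features), 0)
  expect_equal(nrow(g$edges), 0)
  expect_equal(g$n_windows, 0)
  expect_warning(
    encode_dataset(tibble::tibble(id = "s1", sequence = "AC"),
                   encoder_config(k = 3, d = 3)),
    "empty graphs")
})

test_that("edge weights sum to n_windows - 1 and features sum to 1", {
  set.seed(24)
  for (rep in 1:10) {
    s <- random_dna(sample(10:200, 1))
    k <- sample(1:3, 1)
    d <- sample(1:3, 1)
    if (k == 1) d <- 1
    g <- sequence_feature_graph(s, encoder_config(k = k, d = d))
    expect_equal(sum(g$edges$weight), max(0, g$n_windows - 1))
    if (g$n_windows > 0) {
      # pooled divisor keeps relative features summing to 1 even with gaps
      expect_equal(sum(g$node_features), 1, tolerance = 1e-9)
    }
  }
})

test_that("graph construction ignores FASTA line wrapping and case", {
  s <- "GTACTAGGCATTACGATCGA"
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s", substr(tolower(s), 1, 7), substr(tolower(s), 8, 20)), fa)
  ds <- read_fasta(fa)
  cfg <- encoder_config(k = 3, d = 3)
  expect_equal(sequence_feature_graph(ds$sequence[1], cfg),
               sequence_feature_graph(s, cfg))
})

test_that("the k-mer universe is lexicographic with 4^k entries", {
  u3 <- kmer_universe(3)
  expect_length(u3, 64)
  expect_identical(u3, sort(u3))
  expect_equal(u3[1:5], c("AAA", "AAC", "AAG", "AAT", "ACA"))
  expect_error(kmer_universe(9), "<= 8")
})

test_that("graphs serialize to plain-text node and edge tables", {
  g <- sequence_feature_graph("GTACTA", encoder_config(k = 2, d = 1))
  stem <- file.path(withr::local_tempdir(), "g1")
  paths <- write_sfg(g, stem)
  nodes <- readr::read_tsv(paths["nodes"], show_col_types = FALSE)
  edges <- readr::read_tsv(paths["edges"], show_col_types = FALSE)
  expect_equal(nrow(nodes), 16)
  expect_equal(nrow(edges), 4)
  expect_equal(sum(nodes$feature), 1)
})
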