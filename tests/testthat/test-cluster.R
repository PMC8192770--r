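test_that("error-free reads with multiplicity m count exactly m per reference", {
  set.seed(51)
  refs <- tibble::tibble(id = sprintf("r%02d", 1:20),
                         seq = random_dna_str(20, 200))
  m <- 7L
  reads <- rep(refs$seq, each = m)
  cl <- cluster_reads(reads, refs)
  expect_identical(cl$references$adjusted_count, rep(7, 20))
  expect_identical(cl$references$raw_size, rep(27, 20))
  expect_identical(nrow(cl$unassigned), 0L)
})

test_that("the Levenshtein threshold is a sharp boundary at 8 edits", {
  set.seed(52)
  refs <- tibble::tibble(id = c("a", "b"), seq = random_dna_str(2, 200))
  mutate_n <- function(s, n) {
    v <- strsplit(s, "")[[1]]
    pos <- sample(length(v), n)
    for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
    paste(v, collapse = "")
  }
  r8 <- mutate_n(refs$seq[1], 8)
  r9 <- mutate_n(refs$seq[1], 9)
  stopifnot(edit_distance(refs$seq[1], r8) == 8,
            edit_distance(refs$seq[1], r9) == 9)
  cl <- cluster_reads(c(r8, r9), refs)
  expect_identical(cl$references$adjusted_count[cl$references$id == "a"], 1)
  expect_identical(nrow(cl$unassigned), 1L)
  expect_identical(cl$unassigned$seq, r9)
})

test_that("references alone report zero adjusted counts", {
  set.seed(53)
  refs <- tibble::tibble(id = sprintf("r%02d", 1:10),
                         seq = random_dna_str(10, 200))
  cl <- cluster_reads(character(0), refs)
  expect_identical(cl$references$adjusted_count, rep(0, 10))
  expect_identical(cl$references$raw_size, rep(20, 10))
})

test_that("counts conserve reads and are invariant to read order", {
  set.seed(54)
  refs <- tibble::tibble(id = sprintf("r%02d", 1:30),
                         seq = random_dna_str(30, 200))
  pool <- tibble::tibble(id = refs$id, seq = refs$seq, abundance = 1)
  reads <- make_noisy_reads(pool, per_base_error = 0.02, depth = 12, seed = 9)
  cl <- cluster_reads(reads, refs)
  g <- glance(cl)
  expect_equal(g$reads_to_references + g$reads_unassigned, as.numeric(g$n_reads))
  shuffled <- reads[sample(nrow(reads)), ]
  cl2 <- cluster_reads(shuffled, refs)
  expect_identical(cl$references, cl2$references)
  # length filter removes truncated products and keeps conservation
  trunc <- substr(refs$seq[1], 1, 100)
  cl3 <- cluster_reads(c(reads$seq, trunc), refs, cluster_config())
  expect_identical(cl3$n_filtered, 1L)
  g3 <- glance(cl3)
  expect_equal(g3$reads_to_references + g3$reads_unassigned, as.numeric(g3$n_reads))
})

test_that("the cluster ratio gate keeps similar references apart", {
  set.seed(55)
  base <- random_dna_str(1, 200)
  v <- strsplit(base, "")[[1]]
  v[5] <- setdiff(c("A", "C", "G", "T"), v[5])[1]
  v[100] <- setdiff(c("A", "C", "G", "T"), v[100])[1]
  near <- paste(v, collapse = "") # 2 edits from base: within the cap
  refs <- tibble::tibble(id = c("a", "b"), seq = c(base, near))
  reads <- c(rep(base, 10), rep(near, 3))
  cl <- cluster_reads(reads, refs)
  # both references keep their own clusters (20+reads vs 5x rule)
  expect_identical(cl$references$adjusted_count[cl$references$id == "a"], 10)
  expect_identical(cl$references$adjusted_count[cl$references$id == "b"], 3)
})
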