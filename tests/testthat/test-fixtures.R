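test_that("progressive JPEG fixtures are deterministic and well-formed", {
  j1 <- make_progressive_jpeg(64, 64, "gradient", 75, seed = 3)
  j2 <- make_progressive_jpeg(64, 64, "gradient", 75, seed = 3)
  expect_identical(j1, j2)
  expect_identical(j1[1:2], as.raw(c(0xFF, 0xD8)))
  # contains an SOF2 marker; segmentation succeeds
  markers <- which(j1 == as.raw(0xFF))
  expect_true(any(j1[markers + 1L] == as.raw(0xC2)))
  expect_gt(segment_progressive_jpeg(j1)$n_scans, 1L)
  # baseline re-encode of the same pixels is rejected
  jb <- make_progressive_jpeg(64, 64, "gradient", 75, seed = 3,
                              progressive = FALSE)
  expect_error(segment_progressive_jpeg(jb),
               class = "dnapreview_unsupported_format")
  jn <- make_progressive_jpeg(32, 32, "noise", 75, seed = 4)
  expect_false(identical(jn, make_progressive_jpeg(32, 32, "noise", 75, seed = 5)))
})

test_that("noisy reads: zero error reproduces strands, coverage is Poisson", {
  set.seed(61)
  pool <- tibble::tibble(id = sprintf("s%03d", 1:50),
                         seq = random_dna_str(50, 200),
                         abundance = rep(c(1, 3), 25))
  r0 <- make_noisy_reads(pool, per_base_error = 0, depth = 5, seed = 2)
  expect_true(all(r0$seq %in% pool$seq))
  # per-strand mean reads proportional to abundance share, within 3 SE
  reads <- make_noisy_reads(pool, per_base_error = 0, depth = 40, seed = 3)
  counts <- table(factor(reads$source, levels = pool$id))
  lam <- 40 * nrow(pool) * pool$abundance / sum(pool$abundance)
  for (grp in c(1, 3)) {
    sel <- pool$abundance == grp
    mu <- mean(counts[sel])
    se <- sqrt(mean(lam[sel]) / sum(sel))
    expect_lt(abs(mu - lam[sel][1]), 3 * se + 0.5)
  }
  expect_identical(make_noisy_reads(pool, 0.01, 5, seed = 9),
                   make_noisy_reads(pool, 0.01, 5, seed = 9))
  # errors perturb roughly per_base_error * length positions
  rn <- make_noisy_reads(pool[1, ], per_base_error = 0.05, depth = 200,
                         indel_fraction = 0, seed = 4)
  d <- vapply(rn$seq, function(s) hamming_distance(s, pool$seq[1]), integer(1))
  expect_gt(mean(d), 0.03 * 200)
  expect_lt(mean(d), 0.07 * 200)
})
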