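test_that("GF(256) arithmetic is a field", {
  a <- 1:255
  expect_true(all(dnapreview:::gf_mul(a, dnapreview:::gf_inv(a)) == 1L))
  expect_true(all(dnapreview:::gf_mul(a, 1L) == a))
  expect_true(all(dnapreview:::gf_mul(a, 0L) == 0L))
  # distributivity spot checks against schoolbook carry-less multiplication
  slow_mul <- function(x, y) {
    r <- 0L
    while (y > 0) {
      if (bitwAnd(y, 1L)) r <- bitwXor(r, x)
      x <- bitwShiftL(x, 1L)
      if (x >= 256L) x <- bitwXor(x, 0x11dL)
      y <- bitwShiftR(y, 1L)
    }
    r
  }
  set.seed(3)
  for (i in 1:50) {
    x <- sample(0:255, 1); y <- sample(0:255, 1)
    expect_identical(dnapreview:::gf_mul(x, y), slow_mul(x, y))
  }
})

test_that("RS encoding is systematic and MDS-consistent", {
  set.seed(11)
  msg <- sample(0:255, 11, TRUE)
  cw <- rs_encode(msg, 3)
  expect_identical(length(cw), 14L)
  expect_identical(cw[1:11], as.integer(msg))
  expect_true(all(dnapreview:::rs_syndromes(cw, 3) == 0L))
  d <- rs_decode(cw, 3)
  expect_true(d$ok)
  expect_identical(d$msg, as.integer(msg))
})

test_that("inner code corrects any single byte error", {
  set.seed(12)
  msg <- sample(0:255, 11, TRUE)
  cw <- rs_encode(msg, 3)
  for (pos in 1:14) {
    bad <- cw
    bad[pos] <- bitwXor(bad[pos], sample(1:255, 1))
    d <- rs_decode(bad, 3)
    expect_true(d$ok)
    expect_identical(d$msg, as.integer(msg))
  }
  # two errors exceed the correction radius t = 1: the decoder either
  # reports failure or lands on a different codeword, never the original
  bad <- cw
  bad[c(2, 9)] <- bitwXor(bad[c(2, 9)], c(5L, 9L))
  d <- rs_decode(bad, 3)
  expect_true(!d$ok || !identical(d$msg, as.integer(msg)))
})

test_that("outer code recovers from erasures up to the MDS bound", {
  set.seed(13)
  msg <- sample(0:255, 185, TRUE)
  cw <- rs_encode(msg, 70)
  for (f in c(1, 35, 70)) {
    er <- sort(sample(255, f))
    bad <- cw; bad[er] <- sample(0:255, f, TRUE)
    d <- rs_decode(bad, 70, erasures = er)
    expect_true(d$ok)
    expect_identical(d$msg, as.integer(msg))
  }
  er <- sort(sample(255, 71))
  bad <- cw; bad[er] <- 0L
  expect_false(rs_decode(bad, 70, erasures = er)$ok)
})

test_that("errors and erasures combine within 2e + f <= d - 1", {
  set.seed(14)
  msg <- sample(0:255, 185, TRUE)
  cw <- rs_encode(msg, 70)
  for (rep in 1:10) {
    e <- sample(0:10, 1)
    f <- sample(0:(70 - 2 * e), 1)
    pos <- sample(255, e + f)
    bad <- cw
    if (e) bad[pos[seq_len(e)]] <- bitwXor(bad[pos[seq_len(e)]],
                                           sample(1:255, e, TRUE))
    if (f) bad[pos[-seq_len(e)]] <- sample(0:255, f, TRUE)
    d <- rs_decode(bad, 70, erasures = pos[-seq_len(e)])
    expect_true(d$ok)
    expect_identical(d$msg, as.integer(msg))
  }
})
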