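test_that("strand count follows ceil(bytes/1665) * 255 and strands are 200 nt", {
  book <- build_codebook()
  one_block <- as.raw(sample(0:255, 1665, TRUE))
  rows <- encode_partition(one_block, book = book)
  expect_identical(nrow(rows), 255L)
  tiny <- encode_partition(as.raw(7), book = book)
  expect_identical(nrow(tiny), 255L) # zero-padded single block
  two <- encode_partition(as.raw(sample(0:255, 1666, TRUE)), book = book)
  expect_identical(nrow(two), 510L)
  lib <- fx_library_small()
  expect_true(all(nchar(lib$strands$seq) == 200L))
  expected <- sum(ceiling(lib$manifest$partition_bytes / 1665) * 255)
  expect_identical(nrow(lib$strands), as.integer(expected))
  # index unique within each partition
  per <- split(lib$strands$index, lib$strands$partition)
  expect_true(all(vapply(per, anyDuplicated, integer(1)) == 0L))
})

test_that("payload re-derivation through codebook and both RS codes is exact", {
  set.seed(21)
  payload <- as.raw(sample(0:255, 400, TRUE))
  rows <- encode_partition(payload)
  pb <- dnapreview:::strand_payload_bytes(paste0(strrep("A", 40), rows$payload,
                                                 strrep("A", 40)))
  # every row is a valid inner codeword carrying (index, data)
  expect_true(all(dnapreview:::rs_clean_rows(pb, 3L)))
  idx <- pb[, 1] * 256L + pb[, 2]
  expect_identical(sort(idx), 0:254)
  d <- decode_strands(pb, length(payload))
  expect_true(d$ok)
  expect_identical(d$bytes, payload)
})

test_that("round trip is the identity on arbitrary random byte payloads", {
  set.seed(22)
  for (rep in 1:20) {
    n <- sample(1:4000, 1)
    payload <- as.raw(sample(0:255, n, TRUE))
    rows <- encode_partition(payload)
    pb <- dnapreview:::strand_payload_bytes(
      paste0(strrep("G", 40), rows$payload, strrep("G", 40)))
    d <- decode_strands(pb, n)
    expect_true(d$ok)
    expect_identical(d$bytes, payload)
  }
})

test_that("any 70 missing rows are recovered; 71 fail the block", {
  set.seed(23)
  payload <- as.raw(sample(0:255, 1665, TRUE))
  rows <- encode_partition(payload)
  pb <- dnapreview:::strand_payload_bytes(
    paste0(strrep("T", 40), rows$payload, strrep("T", 40)))
  for (rep in 1:5) {
    drop <- sample(255, 70)
    d <- decode_strands(pb[-drop, , drop = FALSE], 1665)
    expect_true(d$ok)
    expect_identical(d$bytes, payload)
  }
  drop <- sample(255, 71)
  d <- decode_strands(pb[-drop, , drop = FALSE], 1665)
  expect_false(d$ok)
  expect_false(d$blocks$ok[1])
})

test_that("inner code absorbs one corrupted byte per strand row", {
  set.seed(24)
  payload <- as.raw(sample(0:255, 1665, TRUE))
  rows <- encode_partition(payload)
  pb <- dnapreview:::strand_payload_bytes(
    paste0(strrep("T", 40), rows$payload, strrep("T", 40)))
  hit <- sample(255, 100)
  pb[cbind(hit, sample(14, 100, TRUE))] <- sample(0:255, 100, TRUE)
  d <- decode_strands(pb, 1665)
  expect_true(d$ok)
  expect_identical(d$bytes, payload)
})

test_that("full file round trip reproduces the JPEG byte-for-byte", {
  j <- fx_jpeg_small()
  lib <- fx_library_small()
  dec <- decode_file(lib$strands, lib$manifest)
  expect_true(dec$complete)
  expect_identical(dec$jpeg, j)
  # decoding only partition 1 yields the valid low-resolution prefix
  p1 <- lib$strands[lib$strands$partition == 1, ]
  dec1 <- decode_file(p1, lib$manifest)
  expect_true(dec1$partitions$ok[1])
  expect_false(all(dec1$partitions$ok))
  seg <- segment_progressive_jpeg(j)
  cuts <- lib$manifest$cuts
  expected_prefix <- c(seg$header, do.call(c, seg$scans[seq_len(cuts[1])]),
                       as.raw(c(0xFF, 0xD9)))
  expect_identical(dec1$jpeg, expected_prefix)
})

test_that("payload guard holds: no 20-nt payload window close to any address", {
  lib <- fx_library_small()
  m <- lib$manifest
  probes <- c(m$address_fwd, m$address_rev)
  g <- min_window_hd(substr(lib$strands$seq, 41, 160), probes)
  expect_gte(min(g), 6L)
})

test_that("codebook hash mismatch is a hard decode error", {
  lib <- fx_library_small()
  m <- lib$manifest
  m$codebook_hash <- "0000"
  expect_error(decode_file(lib$strands, m), "hash mismatch")
})
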