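test_that("scan script covers every coefficient once, DC before AC", {
  ss <- build_scan_script()
  expect_identical(nrow(ss), 42L)
  expect_identical(ss[1, ]$band, "Y")
  expect_identical(c(ss$coef_lo[1], ss$coef_hi[1]), c(0L, 0L))
  expect_identical(ss$band[42], "Cr")
  expect_identical(c(ss$coef_lo[42], ss$coef_hi[42]), c(61L, 63L))
  for (b in c("Y", "Cb", "Cr")) {
    covered <- unlist(lapply(which(ss$band == b), function(i)
      ss$coef_lo[i]:ss$coef_hi[i]))
    expect_identical(sort(covered), 0:63)
    expect_identical(anyDuplicated(covered), 0L)
  }
  dc <- which(ss$coef_hi == 0)
  expect_true(all(dc < min(which(ss$coef_lo > 0))))
})

test_that("segmentation is lossless and counts scans like a raw marker scan", {
  j <- fx_jpeg_small()
  seg <- segment_progressive_jpeg(j)
  # independent oracle: count 0xFFDA markers directly in the byte stream,
  # skipping entropy-coded regions is unnecessary for counting SOS because
  # 0xFF in entropy data is always stuffed (0xFF00) or a restart marker
  ff <- which(j == as.raw(0xFF))
  nxt <- as.integer(j[ff + 1L])
  expect_identical(seg$n_scans, sum(nxt == 0xDA))
  expect_identical(c(seg$header, do.call(c, seg$scans), as.raw(c(0xFF, 0xD9))), j)
  expect_identical(seg$sof, as.integer(0xC2))
})

test_that("baseline and truncated streams are rejected", {
  base <- make_progressive_jpeg(32, 32, "gradient", 75, seed = 3,
                                progressive = FALSE)
  expect_error(segment_progressive_jpeg(base),
               class = "dnapreview_unsupported_format")
  j <- fx_jpeg_small()
  expect_error(segment_progressive_jpeg(j[1:(length(j) - 30)]), "truncated")
  expect_error(segment_progressive_jpeg(as.raw(c(1, 2, 3))), "SOI")
})

test_that("partition bookkeeping: tiers increase, copies follow the schedule", {
  seg <- segment_progressive_jpeg(fx_jpeg_small())
  n <- seg$n_scans
  cuts <- c(2, 3, n - 5)
  parts <- partition_scans(seg, cuts)
  expect_identical(parts$n_scans, as.integer(cuts))
  expect_true(all(diff(parts$hd_tier) > 0))
  expect_identical(parts$hd_tier, c(0L, 4L, 6L))
  expect_identical(parts$copies, c(1, 100, 1000))
  expect_identical(sum(parts$n_bytes),
                   length(seg$header) + sum(lengths(seg$scans)))
  expect_error(partition_scans(seg, c(0, 4, n - 4)), "empty")
  expect_error(partition_scans(seg, c(1, 1)), "cover all scans")
})

test_that("reassembly keeps the successful prefix and needs partition 1", {
  pieces <- list(as.raw(1:4), as.raw(5:8), as.raw(9:12))
  out <- reassemble_jpeg(pieces, c(TRUE, TRUE, FALSE))
  expect_identical(out, c(as.raw(1:8), as.raw(c(0xFF, 0xD9))))
  expect_identical(reassemble_jpeg(pieces, c(TRUE, TRUE, TRUE)),
                   c(as.raw(1:12), as.raw(c(0xFF, 0xD9))))
  # a failure hides everything after it, even later successes
  out <- reassemble_jpeg(pieces, c(TRUE, FALSE, TRUE))
  expect_identical(out, c(as.raw(1:4), as.raw(c(0xFF, 0xD9))))
  expect_error(reassemble_jpeg(pieces, c(FALSE, TRUE, TRUE)),
               class = "dnapreview_unreadable_image")
})
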