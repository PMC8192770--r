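# Byte/marker-level handling of progressive JPEG streams. The codec
# partitions a file at scan boundaries; it never touches DCT coefficients or
# entropy coding.

.JPEG <- list(SOI = 0xD8, EOI = 0xD9, SOS = 0xDA, SOF0 = 0xC0, SOF2 = 0xC2)

#' The 42-scan progressive script used for Preview encoding
#'
#' Spectral-selection scan ordering: the three DC scans (Y, Cr, Cb) followed
#' by the luminance AC coefficients in groups of five (final group 61:63),
#' then the interleaved Cb/Cr AC groups. Every coefficient 0..63 of every
#' band is covered exactly once and DC scans precede all AC scans.
#'
#' @return tibble with columns `scan`, `band`, `coef_lo`, `coef_hi` (42 rows).
#' @export
build_scan_script <- function() {
  ac_breaks <- cbind(lo = c(seq(1, 56, by = 5), 61),
                     hi = c(seq(5, 60, by = 5), 63))
  rows <- list(tibble(band = c("Y", "Cr", "Cb"), coef_lo = 0L, coef_hi = 0L),
               tibble(band = "Y",
                      coef_lo = as.integer(ac_breaks[, "lo"]),
                      coef_hi = as.integer(ac_breaks[, "hi"])))
  chroma <- tibble(band = rep(c("Cb", "Cr"), nrow(ac_breaks)),
                   coef_lo = as.integer(rep(ac_breaks[, "lo"], each = 2)),
                   coef_hi = as.integer(rep(ac_breaks[, "hi"], each = 2)))
  out <- dplyr::bind_rows(c(rows, list(chroma)))
  out$scan <- seq_len(nrow(out))
  out[, c("scan", "band", "coef_lo", "coef_hi")]
}

.as_jpeg_raw <- function(x) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) abort(sprintf("file not found: %s", x))
    x <- readBin(x, "raw", file.info(x)$size)
  }
  if (!is.raw(x)) abort("expected a raw vector or a file path")
  x
}

#' Split a progressive JPEG into header and scan segments
#'
#' Lossless, byte-level segmentation: the header is everything before the
#' first SOS marker; each segment runs from the end of the previous scan's
#' entropy-coded data (so inter-scan tables travel with the scan they
#' configure) through the end of its own entropy data. Stuffed 0xFF00 bytes
#' and restart markers do not terminate a segment. `header`, the segments
#' and the EOI marker re-concatenate to the input byte-for-byte.
#'
#' @param x raw vector of JPEG bytes, or a file path.
#' @return list with `header` (raw), `scans` (list of raw vectors),
#'   `n_scans`, and `sof` (the frame marker byte, e.g. 0xC2).
#' @export
segment_progressive_jpeg <- function(x) {
  b <- .as_jpeg_raw(x)
  n <- length(b)
  if (n < 4 || b[1] != as.raw(0xFF) || b[2] != as.raw(.JPEG$SOI)) {
    abort("not a JPEG stream (missing SOI marker)")
  }
  i <- 3L
  sof <- NULL
  header_end <- NULL
  scans <- list()
  seg_start <- NULL
  while (i < n) {
    if (b[i] != as.raw(0xFF)) abort(sprintf("parse error: expected marker at byte %d", i))
    m <- as.integer(b[i + 1])
    if (m == 0xFF) { i <- i + 1L; next } # fill byte
    if (m == .JPEG$EOI) break
    if (m %in% c(0x01, 0xD0:0xD7)) { i <- i + 2L; next } # standalone
    if (m == .JPEG$SOF0) {
      abort("baseline JPEG (SOF0): Preview encoding requires progressive input",
            class = "dnapreview_unsupported_format")
    }
    if (m %in% c(0xC1, 0xC3, 0xC5:0xC7, 0xC9:0xCB, 0xCD:0xCF)) {
      abort(sprintf("unsupported JPEG frame type 0x%X", m),
            class = "dnapreview_unsupported_format")
    }
    if (m == .JPEG$SOF2) sof <- m
    if (i + 3L > n) abort("truncated JPEG stream")
    len <- as.integer(b[i + 2]) * 256L + as.integer(b[i + 3])
    if (m == .JPEG$SOS) {
      if (is.null(sof)) abort("SOS before SOF2: not a progressive JPEG",
                              class = "dnapreview_unsupported_format")
      if (is.null(header_end)) header_end <- i - 1L
      if (is.null(seg_start)) seg_start <- i
      # skip scan header then entropy-coded data
      j <- i + 2L + len
      while (j < n) {
        if (b[j] == as.raw(0xFF)) {
          nxt <- as.integer(b[j + 1])
          if (nxt != 0x00 && !(nxt %in% 0xD0:0xD7)) break
          j <- j + 2L
        } else j <- j + 1L
      }
      if (j >= n) abort("truncated JPEG stream inside entropy-coded data")
      scans[[length(scans) + 1L]] <- b[seg_start:(j - 1L)]
      seg_start <- j
      i <- j
    } else {
      i <- i + 2L + len
    }
  }
  if (i >= n || b[i + 1] != as.raw(.JPEG$EOI)) abort("truncated JPEG stream (no EOI)")
  if (!length(scans)) abort("no SOS scans found")
  # bytes between the last entropy data and EOI stay with the last scan
  if (seg_start < i) {
    scans[[length(scans)]] <- c(scans[[length(scans)]], b[seg_start:(i - 1L)])
  }
  list(header = b[seq_len(header_end)], scans = scans,
       n_scans = length(scans), sof = sof)
}

#' Choose partition cut points for a segmented JPEG
#'
#' Partition 1 takes the header plus as many leading scans as fit within
#' `first_max_bytes` (at least one scan); the remaining scans are split into
#' `n_partitions - 1` contiguous groups of approximately equal byte size.
#'
#' @param seg result of [segment_progressive_jpeg()].
#' @param n_partitions total partitions (3 or 4 typical).
#' @param first_max_bytes byte budget for partition 1 (default one RS block,
#'   1665 bytes).
#' @return integer vector of scan counts per partition (sums to n_scans).
#' @export
choose_partition_cuts <- function(seg, n_partitions = 3L,
                                  first_max_bytes = 1665L) {
  sizes <- vapply(seg$scans, length, integer(1))
  if (n_partitions < 2L || n_partitions > seg$n_scans) {
    abort("n_partitions must lie in [2, n_scans]")
  }
  cum <- length(seg$header) + cumsum(sizes)
  k1 <- max(1L, sum(cum <= first_max_bytes))
  k1 <- min(k1, seg$n_scans - (n_partitions - 1L))
  rest <- sizes[(k1 + 1L):seg$n_scans]
  target <- cumsum(rest) / sum(rest) * (n_partitions - 1L)
  grp <- pmin(n_partitions - 1L, floor(target) + 1L)
  grp[length(grp)] <- n_partitions - 1L
  counts <- c(k1, as.integer(table(factor(grp, levels = seq_len(n_partitions - 1L)))))
  if (any(counts <= 0L)) abort("empty partition produced; reduce n_partitions")
  counts
}

#' Group JPEG scans into HD-tiered partitions
#'
#' Partition 1 holds the JPEG header plus its scans; each later partition is
#' the concatenation of its scans. Higher-numbered partitions receive
#' strictly greater Hamming-distance tiers and the stored-copy schedule.
#'
#' @param seg result of [segment_progressive_jpeg()].
#' @param cuts integer vector of scan counts per partition (must cover all
#'   scans), e.g. from [choose_partition_cuts()].
#' @param hd_tiers HD tier per partition; default `c(0,4,6)` for three
#'   partitions, `c(0,2,4,6)` for four.
#' @param copies stored-copy multiplier per partition; default `c(1,100,1000)`
#'   for three partitions, `c(1,10,100,1000)` for four.
#' @return tibble with columns `partition`, `n_scans`, `hd_tier`, `copies`,
#'   `n_bytes` and a list column `bytes`.
#' @export
partition_scans <- function(seg, cuts, hd_tiers = NULL, copies = NULL) {
  np <- length(cuts)
  if (sum(cuts) != seg$n_scans) abort("cuts must cover all scans exactly")
  if (any(cuts <= 0L)) abort("empty partition requested")
  if (is.null(hd_tiers)) {
    hd_tiers <- switch(as.character(np), "2" = c(0L, 4L), "3" = c(0L, 4L, 6L),
                       "4" = c(0L, 2L, 4L, 6L),
                       abort("provide hd_tiers for this partition count"))
  }
  if (is.null(copies)) {
    copies <- switch(as.character(np), "2" = c(1, 100), "3" = c(1, 100, 1000),
                     "4" = c(1, 10, 100, 1000),
                     abort("provide copies for this partition count"))
  }
  if (any(diff(hd_tiers) <= 0)) abort("hd tiers must strictly increase with partition ordinal")
  ends <- cumsum(cuts)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  bytes <- lapply(seq_len(np), function(p) {
    body <- do.call(c, seg$scans[starts[p]:ends[p]])
    if (p == 1L) c(seg$header, body) else body
  })
  tibble(partition = seq_len(np), n_scans = as.integer(cuts),
         hd_tier = as.integer(hd_tiers), copies = as.numeric(copies),
         n_bytes = vapply(bytes, length, integer(1)), bytes = bytes)
}

#' Reassemble a JPEG from decoded partitions
#'
#' Concatenates the successfully decoded prefix of partitions in ordinal
#' order, drops everything at and after the first failed partition, and
#' appends the EOI marker. Losing only trailing partitions reduces image
#' quality; losing partition 1 (header + first scans) makes the file
#' unreadable.
#'
#' @param partition_bytes list of raw vectors, one per partition ordinal
#'   (failed entries may be NULL).
#' @param ok logical vector: did each partition decode.
#' @return raw vector: a parseable JPEG stream.
#' @export
reassemble_jpeg <- function(partition_bytes, ok) {
  if (!isTRUE(ok[1])) {
    abort("partition 1 missing or failed: image is unreadable",
          class = "dnapreview_unreadable_image")
  }
  keep <- seq_len(if (all(ok)) length(ok) else min(which(!ok)) - 1L)
  c(do.call(c, partition_bytes[keep]), as.raw(c(0xFF, 0xD9)))
}
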