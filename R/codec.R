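# Strand-level encoder/decoder: two-level Reed-Solomon protection, the
# comma-free codebook, restriction-site insertion and primer framing.

#' Code parameters of the strand layout
#'
#' Outer code \[255, 185, 71\] over GF(256) applied column-wise across the
#' strands of a block; inner code \[14, 11, 4\] protecting the 2-byte row
#' index plus 9 data bytes of each strand. One block of 1665 bytes = 185
#' rows x 9 columns; each encoded row becomes 14 codewords of 8 nt, split
#' around an 8-nt restriction site, framed by 20-nt partition addresses and
#' 20-nt flanking primers: a 200-nt strand.
#'
#' @param outer_n,outer_k outer code length and dimension (255, 185).
#' @param inner_n,inner_k inner code length and dimension (14, 11).
#' @param index_bytes width of the per-partition row index (2).
#' @param codeword_nt codeword length (8).
#' @param primer_nt primer/address length (20).
#' @param site_nt restriction-site length (8).
#' @return list of class `code_parameters` with derived fields
#'   `block_bytes`, `block_cols`, `outer_d`, `inner_d`, `strand_nt`.
#' @export
code_parameters <- function(outer_n = 255L, outer_k = 185L,
                            inner_n = 14L, inner_k = 11L,
                            index_bytes = 2L, codeword_nt = 8L,
                            primer_nt = 20L, site_nt = 8L) {
  block_cols <- inner_k - index_bytes
  p <- list(outer_n = outer_n, outer_k = outer_k,
            outer_d = outer_n - outer_k + 1L,
            inner_n = inner_n, inner_k = inner_k,
            inner_d = inner_n - inner_k + 1L,
            index_bytes = index_bytes, block_cols = block_cols,
            block_rows = outer_k, block_bytes = outer_k * block_cols,
            codeword_nt = codeword_nt, primer_nt = primer_nt,
            site_nt = site_nt,
            strand_nt = 4L * primer_nt + inner_n * codeword_nt + site_nt)
  structure(p, class = "code_parameters")
}

# synthetic restriction sites, one per HD tier; common 6-cutter recognition
# sequences padded to 8 nt
.RESTRICTION_SITES <- c("GAATTCAT", "GGATCCTA", "AAGCTTCA", "CTGCAGTA")

restriction_site_for_tier <- function(tier_rank) {
  .RESTRICTION_SITES[((tier_rank - 1L) %% length(.RESTRICTION_SITES)) + 1L]
}

.int_to_bytes2 <- function(x) {
  cbind(x %/% 256L, x %% 256L)
}

#' Encode one partition's bytes into strand rows
#'
#' Pads the payload with zeros to a whole number of 1665-byte blocks,
#' applies the outer \[255,185\] code column-wise within each 185x9 block,
#' prepends each row's 2-byte index (unique within the partition), applies
#' the inner \[14,11\] code, and maps the 14 bytes to 8-nt codewords.
#'
#' @param bytes raw vector of partition payload.
#' @param code [code_parameters()].
#' @param book [build_codebook()].
#' @param site 8-nt restriction site inserted between codewords 7 and 8.
#' @return tibble with columns `block`, `row`, `index` and `payload`
#'   (the 120-nt codeword/site region of each strand).
#' @export
encode_partition <- function(bytes, code = code_parameters(),
                             book = build_codebook(),
                             site = .RESTRICTION_SITES[1]) {
  if (!length(bytes)) abort("cannot encode an empty partition")
  v <- as.integer(bytes)
  pad <- (-length(v)) %% code$block_bytes
  v <- c(v, integer(pad))
  nblocks <- length(v) / code$block_bytes
  total_rows <- nblocks * code$outer_n
  if (total_rows > 2^(8L * code$index_bytes)) {
    abort(sprintf("partition needs %d rows, exceeding the %d-byte index capacity",
                  total_rows, code$index_bytes),
          class = "dnapreview_capacity_error")
  }
  out <- vector("list", nblocks)
  for (b in seq_len(nblocks)) {
    blk <- v[((b - 1L) * code$block_bytes + 1L):(b * code$block_bytes)]
    m <- matrix(blk, nrow = code$block_rows, ncol = code$block_cols, byrow = TRUE)
    ext <- t(rs_encode_matrix(t(m), code$outer_n - code$outer_k))
    idx <- (b - 1L) * code$outer_n + seq_len(code$outer_n) - 1L
    msg <- cbind(.int_to_bytes2(idx), ext)
    cw <- rs_encode_matrix(msg, code$inner_n - code$inner_k)
    words <- matrix(book_encode(cw, book), nrow = code$outer_n)
    payload <- paste0(
      apply(words[, 1:7, drop = FALSE], 1, paste, collapse = ""),
      site,
      apply(words[, 8:14, drop = FALSE], 1, paste, collapse = ""))
    out[[b]] <- tibble(block = b, row = seq_len(code$outer_n),
                       index = idx, payload = payload)
  }
  dplyr::bind_rows(out)
}

# extract the 14 codeword bytes from full strands (or 120-nt payloads)
strand_payload_bytes <- function(seqs, code = code_parameters(),
                                 book = build_codebook()) {
  L <- nchar(seqs[1])
  off <- if (L == code$strand_nt) 2L * code$primer_nt else 0L
  starts <- off + c(seq(1L, by = code$codeword_nt, length.out = 7L),
                    7L * code$codeword_nt + code$site_nt +
                      seq(1L, by = code$codeword_nt, length.out = 7L))
  words <- vapply(starts, function(s)
    substr(seqs, s, s + code$codeword_nt - 1L), character(length(seqs)))
  if (length(seqs) == 1L) words <- matrix(words, nrow = 1)
  matrix(book_decode(words, book), nrow = length(seqs))
}

#' Decode recovered strand rows into partition bytes
#'
#' Inner-decodes each 14-byte row (correcting up to one byte error),
#' deduplicates rows by index with a per-byte majority vote, places rows
#' into blocks, treats absent rows as erasures, and erasure-decodes the
#' outer code column-wise. A block fails (without raising) when more than
#' `outer_d - 1 = 70` of its rows are missing.
#'
#' @param payload_bytes integer matrix, one 14-byte inner codeword per row
#'   (e.g. from [strand_payload_bytes()]).
#' @param n_bytes true (unpadded) partition length; padding is stripped.
#' @param code [code_parameters()].
#' @return list with `bytes` (raw, NULL if any block failed is still
#'   returned for the successful prefix handling upstream), `ok` (all blocks
#'   good) and `blocks` (tibble: block, rows_present, ok).
#' @export
decode_strands <- function(payload_bytes, n_bytes, code = code_parameters()) {
  nsym_i <- code$inner_n - code$inner_k
  nsym_o <- code$outer_n - code$outer_k
  nblocks <- ceiling(n_bytes / code$block_bytes)
  rows_ok <- list()
  if (nrow(payload_bytes)) {
    clean <- rs_clean_rows(payload_bytes, nsym_i)
    msgs <- matrix(NA_integer_, nrow(payload_bytes), code$inner_k)
    msgs[clean, ] <- payload_bytes[clean, seq_len(code$inner_k), drop = FALSE]
    for (i in which(!clean)) {
      d <- rs_decode(payload_bytes[i, ], nsym_i)
      if (d$ok) msgs[i, ] <- d$msg
    }
    good <- !is.na(msgs[, 1])
    msgs <- msgs[good, , drop = FALSE]
  } else {
    msgs <- matrix(integer(0), 0, code$inner_k)
  }
  idx <- msgs[, 1] * 256L + msgs[, 2]
  data <- msgs[, -(1:2), drop = FALSE]
  # majority vote across duplicate indices
  if (anyDuplicated(idx)) {
    o <- order(idx)
    idx <- idx[o]; data <- data[o, , drop = FALSE]
    grp <- cumsum(!duplicated(idx))
    uidx <- idx[!duplicated(idx)]
    voted <- matrix(0L, length(uidx), ncol(data))
    for (g in seq_along(uidx)) {
      rows <- data[grp == g, , drop = FALSE]
      voted[g, ] <- apply(rows, 2, function(col) {
        tb <- sort(table(col), decreasing = TRUE)
        as.integer(names(tb)[1])
      })
    }
    idx <- uidx; data <- voted
  }
  blocks <- vector("list", nblocks)
  status <- logical(nblocks)
  present <- integer(nblocks)
  for (b in seq_len(nblocks)) {
    lo <- (b - 1L) * code$outer_n
    sel <- idx >= lo & idx < lo + code$outer_n
    rpos <- idx[sel] - lo + 1L
    present[b] <- length(unique(rpos))
    ext <- matrix(0L, code$outer_n, code$block_cols)
    ext[rpos, ] <- data[sel, , drop = FALSE]
    missing <- setdiff(seq_len(code$outer_n), rpos)
    if (length(missing) > nsym_o) { status[b] <- FALSE; next }
    cols <- matrix(0L, code$block_rows, code$block_cols)
    ok <- TRUE
    for (j in seq_len(code$block_cols)) {
      d <- rs_decode(ext[, j], nsym_o, erasures = missing)
      if (!d$ok) { ok <- FALSE; break }
      cols[, j] <- d$msg
    }
    status[b] <- ok
    if (ok) blocks[[b]] <- as.integer(t(cols)) # row-major block bytes
  }
  bytes <- NULL
  if (all(status)) {
    bytes <- as.raw(utils::head(unlist(blocks), n_bytes))
  }
  list(bytes = bytes, ok = all(status),
       blocks = tibble(block = seq_len(nblocks), rows_present = present,
                       ok = status))
}

# mutual dissimilarity screen for flank + base address primers
.design_primer_panel <- function(n, min_hd = 8L, ...) {
  primers <- character(0)
  for (tries in seq_len(200L)) {
    cand <- .generate_primers(1L, ...)
    if (all(vapply(primers, function(p)
      hamming_distance(p, cand) >= min_hd, logical(1)))) {
      primers <- c(primers, cand)
      if (length(primers) == n) return(primers)
    }
  }
  abort("could not design a mutually dissimilar primer panel")
}

#' Encode a progressive JPEG into a tiered Preview strand library
#'
#' Full encoding pipeline: segment the JPEG at scan boundaries, group scans
#' into partitions, design flanking and base address primers plus
#' HD-tiered address variants, Reed-Solomon encode each partition, assemble
#' 200-nt strands, and verify the payload-versus-address guard (every 20-nt
#' window between the addresses must be at least `guard_min_hd` from every
#' address; violating partitions get fresh addresses).
#'
#' @param jpeg raw vector or file path of a progressive JPEG.
#' @param n_partitions number of partitions (default 3).
#' @param seed integer seed governing primer/address design.
#' @param hd_tiers,copies per-partition tier and stored-copy overrides, see
#'   [partition_scans()].
#' @param code,book see [code_parameters()], [build_codebook()].
#' @param guard_min_hd payload window guard threshold (default 6).
#' @param label file label used in strand ids.
#' @return list of class `preview_library`: `strands` (tibble: id,
#'   partition, hd_tier, copies, block, row, index, seq) and `manifest`.
#' @export
encode_file <- function(jpeg, n_partitions = 3L, seed = 1L,
                        hd_tiers = NULL, copies = NULL,
                        code = code_parameters(), book = build_codebook(),
                        guard_min_hd = 6L, label = "file") {
  seg <- segment_progressive_jpeg(jpeg)
  cuts <- choose_partition_cuts(seg, n_partitions,
                                first_max_bytes = code$block_bytes)
  parts <- partition_scans(seg, cuts, hd_tiers, copies)
  withr::with_seed(derive_seed(seed, "primer-design"), {
    # payloads first: they are independent of the addresses, so the guard can
    # redraw addresses against the fixed payload windows
    rows_all <- vector("list", nrow(parts))
    for (p in seq_len(nrow(parts))) {
      rows <- encode_partition(parts$bytes[[p]], code, book,
                               restriction_site_for_tier(p))
      rows$partition <- p
      rows$hd_tier <- parts$hd_tier[p]
      rows$copies <- parts$copies[p]
      rows_all[[p]] <- rows
    }
    payloads <- unlist(lapply(rows_all, `[[`, "payload"))
    guard_ok <- function(seqs) {
      min(min_window_hd(payloads, seqs)) >= guard_min_hd
    }
    # the base pair is the tier-0 address: draw the primer panel until the
    # base pair itself clears the payload guard
    panel <- NULL
    for (attempt in seq_len(100L)) {
      cand <- .design_primer_panel(4L)
      if (guard_ok(cand[3:4])) { panel <- cand; break }
    }
    if (is.null(panel)) abort("payload guard unsatisfiable for this input")
    flank <- panel[1:2]
    base <- panel[3:4]
    addr <- generate_address_set(base[1], base[2], hd_levels = parts$hd_tier,
                                 count_per_level = 1L)
    # redraw higher-tier addresses individually until each passes the guard
    for (i in which(addr$level > 0)) {
      for (retry in seq_len(400L)) {
        if (guard_ok(c(addr$fwd[i], addr$rev[i]))) break
        if (retry == 400L) abort("payload guard unsatisfiable for this input")
        fresh <- generate_address_set(base[1], base[2],
                                      hd_levels = addr$level[i],
                                      count_per_level = 1L)
        addr[i, c("fwd", "rev")] <- fresh[1, c("fwd", "rev")]
      }
    }
    for (p in seq_len(nrow(parts))) {
      apair <- addr[addr$level == parts$hd_tier[p], ][1, ]
      rows_all[[p]]$seq <- paste0(flank[1], apair$fwd, rows_all[[p]]$payload,
                                  revcomp(apair$rev), revcomp(flank[2]))
    }
  })
  strands <- dplyr::bind_rows(rows_all)
  strands$id <- sprintf("%s|partition=%d|block=%d|row=%d|copies=%d",
                        label, strands$partition, strands$block,
                        strands$row, as.integer(strands$copies))
  strands <- strands[, c("id", "partition", "hd_tier", "copies",
                         "block", "row", "index", "seq")]
  manifest <- list(
    tool = "dnapreview", version = "0.1.0", label = label, seed = seed,
    n_partitions = n_partitions, cuts = cuts,
    partition_bytes = parts$n_bytes, hd_tiers = parts$hd_tier,
    copies = parts$copies,
    flank_fwd = flank[1], flank_rev = flank[2],
    base_fwd = base[1], base_rev = base[2],
    address_fwd = addr$fwd, address_rev = addr$rev,
    sites = vapply(seq_len(nrow(parts)), restriction_site_for_tier, character(1)),
    codebook_hash = book$hash,
    code = unclass(code)[c("outer_n", "outer_k", "inner_n", "inner_k",
                           "index_bytes", "codeword_nt", "primer_nt", "site_nt")])
  structure(list(strands = strands, manifest = manifest),
            class = "preview_library")
}

#' Decode a strand library (or accessed subset) back to a JPEG
#'
#' Partitions are decoded independently; the JPEG is reassembled from the
#' successful prefix of partitions. Strands may come straight from an
#' encoded library, from [simulate_access()] output, or from per-reference
#' cluster counts (pass `counts` to drop references without read support).
#'
#' @param strands tibble with at least `partition` and `seq` columns.
#' @param manifest manifest from [encode_file()] (or a compatible list).
#' @param counts optional tibble `(id, adjusted_count)`; strands whose id has
#'   `adjusted_count < min_reads` are treated as missing.
#' @param min_reads minimum adjusted reads for a strand to count as
#'   recovered (default 1).
#' @param book codebook; its hash must match the manifest.
#' @return list of class `preview_decode`: `jpeg` (raw), `partitions`
#'   (tibble: partition, ok, rows_present), `complete` (all partitions ok).
#' @export
decode_file <- function(strands, manifest, counts = NULL, min_reads = 1L,
                        book = build_codebook()) {
  if (!identical(book$hash, manifest$codebook_hash)) {
    abort("codebook hash mismatch between decoder and manifest")
  }
  cp <- manifest$code
  code <- code_parameters(outer_n = cp$outer_n, outer_k = cp$outer_k,
                          inner_n = cp$inner_n, inner_k = cp$inner_k,
                          index_bytes = cp$index_bytes,
                          codeword_nt = cp$codeword_nt,
                          primer_nt = cp$primer_nt, site_nt = cp$site_nt)
  if (!is.null(counts)) {
    keep <- counts$id[counts$adjusted_count >= min_reads]
    strands <- strands[strands$id %in% keep, , drop = FALSE]
  }
  np <- manifest$n_partitions
  bytes <- vector("list", np)
  ok <- logical(np)
  blocks <- vector("list", np)
  rows_present <- integer(np)
  for (p in seq_len(np)) {
    sub <- strands[strands$partition == p, , drop = FALSE]
    pb <- if (nrow(sub)) strand_payload_bytes(sub$seq, code) else
      matrix(integer(0), 0, code$inner_n)
    d <- decode_strands(pb, manifest$partition_bytes[p], code)
    bytes[[p]] <- d$bytes
    ok[p] <- d$ok
    rows_present[p] <- sum(d$blocks$rows_present)
    blocks[[p]] <- d$blocks
  }
  jpeg <- reassemble_jpeg(bytes, ok)
  structure(list(jpeg = jpeg,
                 partitions = tibble(partition = seq_len(np), ok = ok,
                                     rows_present = rows_present),
                 complete = all(ok)),
            class = "preview_decode")
}
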