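# GC-balanced comma-free codebook: byte -> 8-nt codeword.

.book_env <- new.env(parent = emptyenv())

#' Build the byte-to-codeword codebook
#'
#' Greedy construction over all 4^8 candidate 8-mers in lexicographic order
#' (A < C < G < T): a candidate is accepted when it is GC-balanced (exactly
#' 4 of G/C in 8 nt) and has edit distance >= 2 to every previously accepted
#' codeword; construction stops at 256 codewords. Byte values 0..255 are
#' assigned in acceptance order. The construction is deterministic, so every
#' encoder/decoder pair derives the same book; its MD5 identity hash is
#' recorded in manifests to guard against mismatched variants.
#'
#' @param size number of codewords (default 256, one per byte value).
#' @param word_nt codeword length in nt (default 8).
#' @param min_edit minimum pairwise edit distance (default 2).
#' @return object of class `dna_codebook`: list with `codewords` (character
#'   vector, index = byte value + 1), `word_nt`, `min_edit` and `hash`.
#' @export
build_codebook <- function(size = 256L, word_nt = 8L, min_edit = 2L) {
  key <- paste(size, word_nt, min_edit, sep = "-")
  if (!is.null(.book_env[[key]])) return(.book_env[[key]])
  # all GC-balanced word_nt-mers in lexicographic order
  grid <- do.call(expand.grid,
                  c(rep(list(DNA_BASES), word_nt), stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; reorder columns so that
  # candidates enumerate lexicographically
  cand <- do.call(paste0, rev(grid))
  cand <- cand[order(cand)]
  gc_n <- round(gc_fraction(cand) * word_nt)
  cand <- cand[gc_n == word_nt / 2]
  accepted <- character(0)
  for (w in cand) {
    if (length(accepted) &&
        any(utils::adist(w, accepted) < min_edit)) next
    accepted <- c(accepted, w)
    if (length(accepted) == size) break
  }
  if (length(accepted) < size) {
    abort(sprintf("codebook construction exhausted candidates at %d of %d words",
                  length(accepted), size),
          class = "dnapreview_codebook_failure")
  }
  tf <- tempfile()
  writeLines(accepted, tf)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)
  lookup <- stats::setNames(seq_along(accepted) - 1L, accepted)
  book <- structure(list(codewords = accepted, lookup = lookup,
                         word_nt = word_nt, min_edit = min_edit, hash = hash),
                    class = "dna_codebook")
  .book_env[[key]] <- book
  book
}

# bytes (0..255) -> codeword strings
book_encode <- function(bytes, book) book$codewords[as.integer(bytes) + 1L]

# codeword strings -> bytes; codewords not in the book are mapped to their
# nearest accepted codeword (the inner RS code absorbs residual errors)
book_decode <- function(words, book) {
  v <- unname(book$lookup[words])
  miss <- is.na(v)
  if (any(miss)) {
    for (i in which(miss)) {
      d <- utils::adist(words[i], book$codewords)
      v[i] <- which.min(d) - 1L
    }
  }
  as.integer(v)
}
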