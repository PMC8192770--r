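#' @useDynLib dnapreview, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import tibble
#' @importFrom dplyr %>% mutate filter arrange group_by summarise ungroup
#'   bind_rows left_join select n desc across all_of
#' @importFrom rlang .data abort warn
NULL

DNA_BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Split DNA strings into character matrices and back
#' @noRd
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)

.check_dna <- function(x, arg = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    abort(sprintf("%s contains characters outside {A,C,G,T}: %s",
                  arg, paste(utils::head(x[bad], 3), collapse = ", ")))
  }
  invisible(x)
}

#' Reverse complement of DNA sequences
#'
#' @param x character vector of DNA sequences over `{A,C,G,T}` (N allowed).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(seq_chars(x),
         function(v) paste(rev(unname(.COMP[v])), collapse = ""),
         character(1))
}

#' Hamming distance between two equal-length DNA strings
#'
#' Counts positions at which `a` and `b` differ. This is the address-space
#' distance used throughout tier design: a variant binding site "at HD h"
#' differs from the base address at exactly h positions.
#'
#' @param a,b DNA strings of equal length.
#' @return integer count of differing positions.
#' @export
hamming_distance <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  if (length(ra) != length(rb)) {
    abort(sprintf("hamming_distance() needs equal lengths (got %d and %d)",
                  length(ra), length(rb)))
  }
  sum(ra != rb)
}

#' Levenshtein edit distance
#'
#' Unit-cost substitutions, insertions and deletions. Used to screen mutant
#' primers whose edit distance is much lower than their Hamming distance
#' (shifted near-duplicates that still hybridize well).
#'
#' @param a,b character strings (any lengths).
#' @return integer edit distance.
#' @export
edit_distance <- function(a, b) {
  as.integer(utils::adist(a, b))
}

#' GC fraction of DNA sequences
#' @param x character vector of DNA strings.
#' @return numeric vector in \[0, 1\].
#' @export
gc_fraction <- function(x) {
  vapply(x, function(s) {
    r <- charToRaw(s)
    sum(r == charToRaw("G") | r == charToRaw("C")) / length(r)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Longest homopolymer run length
#' @noRd
max_homopolymer <- function(x) {
  vapply(seq_chars(x), function(v) max(rle(v)$lengths), numeric(1))
}

#' Random DNA strings (uniform base composition)
#' @noRd
random_dna <- function(n, length) {
  m <- matrix(sample(DNA_BASES, n * length, replace = TRUE), nrow = n)
  apply(m, 1, paste, collapse = "")
}

# Deterministic child seed from a top-level seed and a stream name, so that
# module-level results are reproducible independently of call order.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

#' Minimum Hamming distance between every k-window of strands and a primer set
#'
#' Slides a window of `nchar(primers[1])` over every strand and reports the
#' smallest Hamming distance to any primer (or its reverse complement).
#' Used as the payload-versus-address guard.
#'
#' @param strands character vector of strands.
#' @param primers character vector of equal-length primers.
#' @return integer vector, one minimum per strand.
#' @export
min_window_hd <- function(strands, primers) {
  probes <- unique(c(primers, revcomp(primers)))
  .Call(`_dnapreview_window_min_hd`, strands, probes)
}
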