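# FASTA/FASTQ and manifest I/O.

.records_tibble <- function(xss, quals = NULL) {
  out <- tibble(id = names(xss), seq = unname(as.character(xss)))
  if (!is.null(quals)) out$qual <- unname(as.character(quals))
  bad <- grepl("[^ACGTN]", out$seq)
  if (any(bad)) {
    abort(sprintf("record %d (%s) contains symbols outside {A,C,G,T,N}",
                  which(bad)[1], out$id[which(bad)[1]]))
  }
  out
}

#' Read a FASTA file into a tibble
#'
#' Sequences are upper-cased; symbols outside \{A,C,G,T,N\} are rejected.
#' gzip-compressed files are read transparently.
#'
#' @param path file path.
#' @return tibble with columns `id`, `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (file.info(path)$size == 0) return(tibble(id = character(0), seq = character(0)))
  xss <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) abort(sprintf("FASTA parse error in %s: %s",
                                                    path, conditionMessage(e))))
  xss <- Biostrings::BStringSet(toupper(as.character(xss)))
  .records_tibble(xss)
}

#' Write strand records to FASTA
#'
#' @param x tibble with `id` and `seq` columns.
#' @param path output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  xss <- Biostrings::BStringSet(x$seq)
  names(xss) <- x$id
  Biostrings::writeXStringSet(xss, path, format = "fasta",
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' @param path file path (`.gz` transparently supported).
#' @return tibble with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (file.info(path)$size == 0) {
    return(tibble(id = character(0), seq = character(0), qual = character(0)))
  }
  xss <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) abort(sprintf("FASTQ parse error in %s: %s",
                                      path, conditionMessage(e))))
  .records_tibble(Biostrings::BStringSet(toupper(as.character(xss))),
                  S4Vectors::mcols(xss)$qualities)
}

#' Write reads to FASTQ (Sanger quality dialect)
#'
#' @param x tibble with `id`, `seq` and optionally `qual` columns.
#' @param path output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  xss <- Biostrings::DNAStringSet(x$seq)
  names(xss) <- x$id
  qual <- if ("qual" %in% names(x)) x$qual else strrep("I", nchar(x$seq))
  Biostrings::writeXStringSet(xss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write / read an encoding manifest
#'
#' The manifest carries everything a decoder needs: code parameters, scan
#' cuts, partition byte lengths, primer and address sequences, restriction
#' sites and the codebook identity hash (a hash mismatch at decode time is a
#' hard error).
#'
#' @param manifest manifest list from [encode_file()].
#' @param path JSON path.
#' @return `path` / the manifest list.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}
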