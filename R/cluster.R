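# Seeded Levenshtein message-passing clustering of sequencing reads.

#' Clustering configuration
#'
#' @param max_levenshtein maximum edit distance for cluster membership
#'   (default 8).
#' @param cluster_ratio a sequence joins centroid V only when V's read count
#'   is at least this multiple of its own (default 5).
#' @param seed_copies pseudo-copies of each reference strand seeded into the
#'   pool so every library strand is guaranteed centroid status (default 20).
#' @param length_range reads outside this length window are filtered out
#'   before clustering (truncated amplification products).
#' @param kmer k-mer size of the candidate index (pigeonhole-exact for reads
#'   of >= (max_levenshtein + 1) * kmer nt).
#' @return list of class `cluster_config`.
#' @export
cluster_config <- function(max_levenshtein = 8L, cluster_ratio = 5L,
                           seed_copies = 20L, length_range = c(150L, 250L),
                           kmer = 12L) {
  stopifnot(max_levenshtein > 0, cluster_ratio > 0, seed_copies > 0, kmer > 3)
  structure(list(max_levenshtein = as.integer(max_levenshtein),
                 cluster_ratio = as.integer(cluster_ratio),
                 seed_copies = as.integer(seed_copies),
                 length_range = as.integer(length_range),
                 kmer = as.integer(kmer)),
            class = "cluster_config")
}

#' Cluster noisy reads against a reference strand library
#'
#' Message-passing Levenshtein clustering seeded with `seed_copies` copies of
#' every reference strand. Unique sequences are processed in descending
#' multiplicity (ties lexicographic); a sequence's reads are attributed to an
#' existing centroid V when their edit distance is at most `max_levenshtein`
#' and V's count is at least `cluster_ratio` times the sequence's count,
#' otherwise the sequence founds its own cluster. Reference centroids are
#' reported with their cluster size adjusted down by the seeded copies;
#' non-reference centroids are reported separately.
#'
#' @param reads tibble with a `seq` column (e.g. from [make_noisy_reads()] or
#'   [read_fastq()]), or a character vector of read sequences.
#' @param references tibble with `id` and `seq` columns (the encoded library).
#' @param config a [cluster_config()].
#' @return list of class `read_clusters`: `references` (id, raw_size,
#'   adjusted_count), `unassigned` (seq, size), `n_reads` (after length
#'   filter), `n_filtered`, `config`.
#' @export
cluster_reads <- function(reads, references, config = cluster_config()) {
  if (!nrow(references)) abort("references must be non-empty")
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  n_in <- length(seqs)
  len <- nchar(seqs)
  seqs <- seqs[len >= config$length_range[1] & len <= config$length_range[2]]
  n_filtered <- n_in - length(seqs)
  # aggregate multiplicities; seed references
  rtab <- table(seqs)
  pool <- tibble(seq = if (length(rtab)) names(rtab) else character(0),
                 reads = as.numeric(rtab))
  refs <- tibble(seq = references$seq, seeds = config$seed_copies)
  pool <- dplyr::full_join(pool, refs, by = "seq")
  pool$reads[is.na(pool$reads)] <- 0
  pool$seeds[is.na(pool$seeds)] <- 0
  pool$count <- pool$reads + pool$seeds
  pool <- pool[order(-pool$count, pool$seq), ]
  assign <- cluster_core(pool$seq, pool$count,
                         config$max_levenshtein, config$cluster_ratio,
                         config$kmer)
  centroid_of <- ifelse(assign < 0, seq_len(nrow(pool)), assign + 1L)
  # cluster sizes in reads (seeds excluded) and seeds, per centroid
  read_size <- tapply(pool$reads, centroid_of, sum)
  seed_size <- tapply(pool$seeds, centroid_of, sum)
  cent_idx <- as.integer(names(read_size))
  cent_seq <- pool$seq[cent_idx]
  sizes <- tibble(seq = cent_seq,
                  reads = as.numeric(read_size),
                  seeds = as.numeric(seed_size))
  ref_counts <- tibble(id = references$id, seq = references$seq) |>
    dplyr::left_join(sizes, by = "seq")
  ref_counts$reads[is.na(ref_counts$reads)] <- 0
  ref_counts$seeds[is.na(ref_counts$seeds)] <- 0
  if (any(ref_counts$seeds == 0)) {
    warn("some reference strands were absorbed into other clusters")
  }
  references_out <- tibble(
    id = ref_counts$id,
    raw_size = ref_counts$reads + ref_counts$seeds,
    adjusted_count = pmax(0, ref_counts$reads +
                            pmin(ref_counts$seeds, config$seed_copies) -
                            config$seed_copies))
  un <- sizes[!(sizes$seq %in% references$seq), c("seq", "reads")]
  names(un) <- c("seq", "size")
  un <- un[un$size > 0, ]
  structure(list(references = references_out,
                 unassigned = un,
                 n_reads = length(seqs), n_filtered = n_filtered,
                 config = config),
            class = "read_clusters")
}
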