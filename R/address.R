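# Tiered address design: a base primer pair plus variant binding sites at
# chosen Hamming distances, and the amplification-tunability statistic.

#' Generate a tiered address set
#'
#' For each requested Hamming-distance level, forward and reverse address
#' variants are produced independently by the substitution walk from the
#' base pair and paired positionally (`pairing = "zip"`) or in all
#' combinations (`pairing = "product"`, the layout of the experimental
#' screen). Candidates must keep their GC fraction inside `gc_range`, pass
#' the edit-distance screen (edit distance strictly greater than
#' `hd - edit_screen_margin`), and stay at least `max(2, |h - g|)` Hamming
#' distance from every accepted site of any other level, preserving clean
#' tier separation.
#'
#' @param base_fwd,base_rev base primer sequences (level 0 binding sites).
#' @param hd_levels integer vector of tier levels (0 allowed; level 0 is the
#'   base pair itself).
#' @param count_per_level variants per level (default 1).
#' @param gc_range allowed GC fraction for variant sites.
#' @param edit_screen_margin see [hyb_config()].
#' @param pairing `"zip"` (positional) or `"product"` (all pairs).
#' @param seed optional integer seed.
#' @param max_attempts per-candidate attempt cap.
#' @return tibble of class `address_set`: columns `level`, `pair`, `fwd`,
#'   `rev`.
#' @export
generate_address_set <- function(base_fwd, base_rev, hd_levels,
                                 count_per_level = 1L,
                                 gc_range = c(0.30, 0.70),
                                 edit_screen_margin = 3L,
                                 pairing = c("zip", "product"),
                                 seed = NULL, max_attempts = 2000L) {
  pairing <- match.arg(pairing)
  if (is.data.frame(base_fwd)) base_fwd <- base_fwd$seq[1]
  if (is.data.frame(base_rev)) base_rev <- base_rev$seq[1]
  .check_dna(c(base_fwd, base_rev), "base primers")
  L <- nchar(base_fwd)
  if (any(hd_levels < 0 | hd_levels > L)) {
    abort(sprintf("hd_levels must lie in [0, %d]", L))
  }
  run <- function() {
    accepted <- list() # per side: tibble(level, seq)
    make_side <- function(base, side) {
      done <- tibble(level = integer(0), seq = character(0))
      for (h in sort(unique(as.integer(hd_levels)))) {
        need <- if (h == 0L) 1L else count_per_level
        got <- 0L
        attempts <- 0L
        while (got < need) {
          if (h == 0L) {
            cand <- base
          } else {
            attempts <- attempts + 1L
            if (attempts > max_attempts) {
              abort(sprintf("address generation failed at level %d (%s side)",
                            h, side),
                    class = "dnapreview_generation_failure")
            }
            cand <- mutate_to_hd(base, h)
            gc <- gc_fraction(cand)
            if (gc < gc_range[1] || gc > gc_range[2]) next
            if (edit_distance(base, cand) <= h - edit_screen_margin) next
            other <- done[done$level != h, ]
            if (nrow(other)) {
              dists <- vapply(other$seq, hamming_distance, integer(1), b = cand)
              if (any(dists < pmax(2L, abs(other$level - h)))) next
            }
          }
          done <- dplyr::bind_rows(done, tibble(level = h, seq = cand))
          got <- got + 1L
        }
      }
      done
    }
    fwd <- make_side(base_fwd, "forward")
    rev_ <- make_side(base_rev, "reverse")
    rows <- lapply(sort(unique(as.integer(hd_levels))), function(h) {
      f <- fwd$seq[fwd$level == h]
      r <- rev_$seq[rev_$level == h]
      if (pairing == "zip") {
        tibble(level = h, pair = seq_along(f), fwd = f, rev = r)
      } else {
        g <- expand.grid(fwd = f, rev = r, stringsAsFactors = FALSE)
        tibble(level = h, pair = seq_len(nrow(g)), fwd = g$fwd, rev = g$rev)
      }
    })
    out <- dplyr::bind_rows(rows)
    class(out) <- c("address_set", class(out))
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Amplification tunability
#'
#' Difference in the nonspecific:specific product ratio between promiscuous
#' and stringent conditions:
#' `(ns/s)_promiscuous - (ns/s)_stringent`. Positive values indicate
#' tunability in the expected direction (mismatched strands amplify under
#' promiscuous but not stringent conditions).
#'
#' @param data optional data frame with columns `ns_promiscuous`,
#'   `s_promiscuous`, `ns_stringent`, `s_stringent`; a `tunability` column
#'   is appended. Otherwise supply the four concentrations directly.
#' @param ns_promiscuous,s_promiscuous nonspecific/specific strand
#'   concentrations under the promiscuous condition (any common unit).
#' @param ns_stringent,s_stringent the same under the stringent condition.
#' @return `data` with a `tunability` column, or a numeric scalar.
#' @export
amplification_tunability <- function(data = NULL, ns_promiscuous,
                                     s_promiscuous, ns_stringent,
                                     s_stringent) {
  if (!is.null(data)) {
    stopifnot(all(c("ns_promiscuous", "s_promiscuous",
                    "ns_stringent", "s_stringent") %in% names(data)))
    data$tunability <- amplification_tunability(
      NULL, data$ns_promiscuous, data$s_promiscuous,
      data$ns_stringent, data$s_stringent)
    return(data)
  }
  if (any(s_promiscuous <= 0) || any(s_stringent <= 0)) {
    abort("specific-strand concentrations must be strictly positive",
          class = "dnapreview_domain_error")
  }
  ns_promiscuous / s_promiscuous - ns_stringent / s_stringent
}
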