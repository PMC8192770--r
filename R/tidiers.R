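# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a hybridization curve
#' @param x a `hyb_curve`.
#' @param ... ignored.
#' @return one row per Hamming distance.
#' @export
tidy.hyb_curve <- function(x, ...) {
  tibble(hd = x$hd, n_kept = x$n_kept, n_bound = x$n_bound,
         fraction_bound = x$fraction_bound,
         se = sqrt(pmax(x$fraction_bound * (1 - x$fraction_bound), 0) /
                     pmax(x$n_kept, 1)))
}

#' @rdname tidy.hyb_curve
#' @export
glance.hyb_curve <- function(x, ...) {
  cfg <- attr(x, "config")
  plateau <- x$hd[which(x$fraction_bound <= 0.01)[1]]
  tibble(n_trials = cfg$n_trials, dG_threshold = cfg$dG_threshold,
         eval_temperature = cfg$eval_temperature,
         plateau_hd = plateau, fraction_at_0 = x$fraction_bound[x$hd == 0][1])
}

#' Tidy an access simulation
#' @param x an `access_result`.
#' @param ... ignored.
#' @return one row per HD tier.
#' @export
tidy.access_result <- function(x, ...) x$tiers

#' @rdname tidy.access_result
#' @export
glance.access_result <- function(x, ...) {
  tibble(label = x$condition$label[1],
         annealing_temperature = x$condition$annealing_temperature[1],
         primer_concentration = x$condition$primer_concentration[1],
         n_tiers = nrow(x$tiers),
         accessed_tiers = paste(x$accessed_tiers, collapse = ","))
}

#' Tidy a competitive PCR simulation
#' @param x a `pcr_amplification`.
#' @param ... ignored.
#' @return one row per species.
#' @export
tidy.pcr_amplification <- function(x, ...) x$species

#' Tidy read clusters
#' @param x a `read_clusters`.
#' @param ... ignored.
#' @return per-reference counts.
#' @export
tidy.read_clusters <- function(x, ...) x$references

#' @rdname tidy.read_clusters
#' @export
glance.read_clusters <- function(x, ...) {
  tibble(n_reads = x$n_reads, n_filtered = x$n_filtered,
         reads_to_references = sum(x$references$adjusted_count),
         reads_unassigned = sum(x$unassigned$size),
         n_unassigned_clusters = nrow(x$unassigned))
}

#' Tidy a decode result
#' @param x a `preview_decode`.
#' @param ... ignored.
#' @return per-partition status.
#' @export
tidy.preview_decode <- function(x, ...) x$partitions
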