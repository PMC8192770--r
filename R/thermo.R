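# Two-state nearest-neighbor duplex thermodynamics and the Monte-Carlo
# hybridization-likelihood model.

R_GAS <- 1.9872e-3  # kcal / (mol K)

# Effective monovalent cation concentration (M) with a sqrt-divalent
# equivalence, and the entropic salt correction of the unified NN model.
.salt_na_eq <- function(monovalent_mM, divalent_mM) {
  (monovalent_mM + 120 * sqrt(max(divalent_mM, 0))) / 1000
}

# Vectorized two-state duplex thermodynamics.
# top: primer strings; bottom_under: for each row, the template bases lying
# under the top strand read 3'->5' (i.e. rev(template)).
.duplex_thermo <- function(top, bottom_under, mismatch_penalty = 1.8) {
  tv <- seq_chars(top)
  uv <- seq_chars(bottom_under)
  n <- length(tv)
  L <- nchar(top[1])
  tm_ <- matrix(unlist(tv), nrow = n, byrow = TRUE)
  um <- matrix(unlist(uv), nrow = n, byrow = TRUE)
  match <- um == matrix(.COMP[tm_], nrow = n)
  i <- seq_len(L - 1)
  keys <- matrix(paste0(tm_[, i, drop = FALSE], tm_[, i + 1, drop = FALSE], "/",
                        um[, i, drop = FALSE], um[, i + 1, drop = FALSE]),
                 nrow = n)
  wc <- match[, i, drop = FALSE] & match[, i + 1, drop = FALSE]
  dh <- matrix(0, n, L - 1); ds <- matrix(0, n, L - 1); pen <- matrix(0, n, L - 1)
  dh[wc] <- .NN_DH[keys[wc]]
  ds[wc] <- .NN_DS[keys[wc]]
  mmh <- .MM_DH[keys[!wc]]
  mms <- .MM_DS[keys[!wc]]
  known <- !is.na(mmh)
  tmp <- dh[!wc]; tmp[known] <- mmh[known]; dh[!wc] <- tmp
  tmp <- ds[!wc]; tmp[known] <- mms[known]; ds[!wc] <- tmp
  tmp <- pen[!wc]; tmp[!known] <- mismatch_penalty; pen[!wc] <- tmp
  dH <- rowSums(dh); dS <- rowSums(ds); penalty <- rowSums(pen)
  for (end in c(1L, L)) {
    ok <- match[, end]
    cls <- ifelse(tm_[, end] %in% c("G", "C"), "GC", "AT")
    dH <- dH + ifelse(ok, .INIT_DH[cls], 0)
    dS <- dS + ifelse(ok, .INIT_DS[cls], 0)
  }
  list(dH = dH, dS = dS, penalty = penalty, length = L)
}

#' Free energy of a primer-template duplex
#'
#' Two-state nearest-neighbor free energy of the duplex formed when `primer`
#' anneals to the equal-length template strand `template` (both written
#' 5'->3'; position i of the primer pairs with position L-i+1 of the
#' template). Watson-Crick stacks use the unified NN parameters; stacks
#' containing a single internal mismatch use the published mismatch
#' parameters; stacks with no published parameters (e.g. tandem mismatches)
#' incur a fixed destabilization penalty. The entropic salt correction uses
#' an effective monovalent concentration with sqrt-divalent equivalence.
#'
#' For a perfectly complementary duplex pass `template = revcomp(primer)`.
#'
#' @param primer,template DNA strings of equal length (>= 2 nt). Vectorized:
#'   both may be vectors of equal length.
#' @param temperature evaluation temperature, degrees C (default 37).
#' @param monovalent monovalent cation concentration, mM (default 1000, the
#'   standard 1 M reference condition).
#' @param divalent divalent cation concentration, mM (default 0).
#' @param mismatch_penalty kcal/mol added per stack lacking published
#'   parameters (default +1.8).
#' @return numeric vector of duplex free energies, kcal/mol.
#' @export
duplex_dG <- function(primer, template, temperature = 37,
                      monovalent = 1000, divalent = 0,
                      mismatch_penalty = 1.8) {
  .check_dna(primer, "primer"); .check_dna(template, "template")
  if (any(nchar(primer) < 2) || any(nchar(template) < 2)) {
    abort("duplex_dG() needs sequences of at least 2 nt")
  }
  if (!all(nchar(primer) == nchar(template))) {
    abort("duplex_dG(): primer and template must have equal lengths")
  }
  bottom <- vapply(seq_chars(template),
                   function(v) paste(rev(v), collapse = ""), character(1))
  th <- .duplex_thermo(primer, bottom, mismatch_penalty)
  tk <- temperature + 273.15
  ds_salt <- th$dS + 0.368 * (th$length - 1) * log(.salt_na_eq(monovalent, divalent))
  th$dH - tk * ds_salt / 1000 + th$penalty
}

#' Nearest-neighbor melting temperature of an oligo
#'
#' Two-state melting temperature of `x` against its perfect complement,
#' for non-self-complementary oligos at total strand concentration `ct`.
#'
#' @param x DNA string(s).
#' @param monovalent,divalent salt, mM. Default 50 mM monovalent, the
#'   convention under which the 50-55 degree primer design window is stated.
#' @param ct total strand concentration, mol/L (default 5e-7).
#' @return melting temperature(s), degrees C.
#' @export
nn_tm <- function(x, monovalent = 50, divalent = 0, ct = 5e-7) {
  .check_dna(x)
  th <- .duplex_thermo(x, vapply(seq_chars(revcomp(x)),
                                 function(v) paste(rev(v), collapse = ""),
                                 character(1)))
  ds_salt <- th$dS + 0.368 * (th$length - 1) * log(.salt_na_eq(monovalent, divalent))
  th$dH * 1000 / (ds_salt + 1.9872 * log(ct / 4)) - 273.15
}

# Bulk rejection sampler for constraint-satisfying primers. Draws batches and
# keeps candidates meeting GC balance, Tm window and homopolymer cap.
.generate_primers <- function(n, length = 20, gc_range = c(0.40, 0.60),
                              tm_range = c(50, 55), max_homopolymer = 4,
                              max_attempts = 200000L) {
  out <- character(0)
  attempts <- 0L
  batch <- max(256L, 4L * n)
  while (length(out) < n) {
    if (attempts >= max_attempts) {
      abort(sprintf(paste0("primer generation failed: constraints not ",
                           "satisfiable within %d attempts (GC %s, Tm %s)"),
                    max_attempts, paste(gc_range, collapse = "-"),
                    paste(tm_range, collapse = "-")),
            class = "dnapreview_generation_failure")
    }
    cand <- random_dna(batch, length)
    attempts <- attempts + batch
    gc <- gc_fraction(cand)
    keep <- gc >= gc_range[1] & gc <= gc_range[2] &
      max_homopolymer(cand) <= max_homopolymer
    cand <- cand[keep]
    if (length(cand)) {
      tm <- nn_tm(cand)
      cand <- cand[tm >= tm_range[1] & tm <= tm_range[2]]
      out <- c(out, cand)
    }
  }
  out[seq_len(n)]
}

#' Design a random data-storage primer
#'
#' Rejection-samples random oligos until one satisfies the field's standard
#' design constraints: GC balance inside `gc_range`, nearest-neighbor melting
#' temperature inside `tm_range`, and no homopolymer run longer than
#' `max_homopolymer`.
#'
#' @param length primer length, nt (default 20).
#' @param gc_range numeric length-2, allowed GC fraction (default 0.40-0.60).
#' @param tm_range numeric length-2, allowed Tm in degrees C (default 50-55).
#' @param max_homopolymer longest allowed single-base run (default 4).
#' @param seed optional integer seed for reproducibility.
#' @param max_attempts candidate cap before a generation-failure error.
#' @return a one-row tibble with columns `seq`, `length`, `gc_fraction`, `tm`.
#' @export
design_random_primer <- function(length = 20, gc_range = c(0.40, 0.60),
                                 tm_range = c(50, 55), max_homopolymer = 4,
                                 seed = NULL, max_attempts = 200000L) {
  run <- function() {
    s <- .generate_primers(1L, length, gc_range, tm_range, max_homopolymer,
                           max_attempts)
    tibble(seq = s, length = nchar(s), gc_fraction = gc_fraction(s),
           tm = nn_tm(s))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Mutate a primer to an exact Hamming distance
#'
#' Random substitution walk: repeatedly pick a uniform position and replace
#' its base with one of the other three until the Hamming distance to the
#' original equals `target_hd`. Positions may be revisited, so the walk can
#' move away from the target before reaching it (repeat-until semantics).
#'
#' @param primer DNA string (or one-row tibble from [design_random_primer()]).
#' @param target_hd target Hamming distance, 0..nchar(primer).
#' @param seed optional integer seed.
#' @param max_iter iteration cap (error if exceeded; the walk terminates with
#'   probability 1 well before this for any feasible target).
#' @return mutated DNA string with exactly the requested Hamming distance.
#' @export
mutate_to_hd <- function(primer, target_hd, seed = NULL, max_iter = 1000000L) {
  if (is.data.frame(primer)) primer <- primer$seq[1]
  .check_dna(primer, "primer")
  if (target_hd < 0 || target_hd > nchar(primer)) {
    abort("target_hd must lie in [0, nchar(primer)]")
  }
  if (target_hd == 0) return(primer)
  run <- function() .Call(`_dnapreview_mutate_walk`, primer,
                          as.integer(target_hd), as.integer(max_iter))
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Configuration for the hybridization Monte-Carlo model
#'
#' @param n_trials Monte-Carlo trials per Hamming distance (default 10000).
#' @param dG_threshold binding threshold, kcal/mol; trials with duplex free
#'   energy below this are classified as binding (default -10).
#' @param eval_temperature temperature for free-energy evaluation, degrees C.
#' @param edit_screen_margin trials whose edit distance is at most
#'   `hd - edit_screen_margin` are screened out as shift-like artifacts.
#' @param rng_seed integer seed governing all randomness in the curve.
#' @param monovalent,divalent salt for the free-energy evaluation, mM.
#' @param primer_length,gc_range,tm_range,max_homopolymer primer design
#'   constraints, see [design_random_primer()].
#' @return a list of class `hyb_config`.
#' @export
hyb_config <- function(n_trials = 10000L, dG_threshold = -10,
                       eval_temperature = 37, edit_screen_margin = 3L,
                       rng_seed = 1L, monovalent = 1000, divalent = 0,
                       primer_length = 20L, gc_range = c(0.40, 0.60),
                       tm_range = c(50, 55), max_homopolymer = 4L) {
  stopifnot(n_trials >= 1, dG_threshold < 0)
  structure(as.list(environment()), class = "hyb_config")
}

#' Hybridization likelihood as a function of Hamming distance
#'
#' Monte-Carlo estimate of the probability that a mutant binding site still
#' hybridizes with its original primer. For each requested Hamming distance,
#' `n_trials` fresh constraint-satisfying primers are drawn, each is mutated
#' to the exact HD by the substitution walk, trials whose edit distance is
#' much lower than their Hamming distance are screened out, and the duplex
#' free energy of the primer against the reverse complement of the mutant is
#' classified against `dG_threshold`.
#'
#' @param hd_values integer vector of Hamming distances (default 0,2,...,20).
#' @param config a [hyb_config()].
#' @return a tibble of class `hyb_curve` with columns `hd`, `n_trials`,
#'   `n_kept`, `n_bound`, `fraction_bound`.
#' @export
hybridization_curve <- function(hd_values = seq(0L, 20L, by = 2L),
                                config = hyb_config()) {
  stopifnot(inherits(config, "hyb_config"))
  if (any(hd_values < 0 | hd_values > config$primer_length)) {
    abort("hd_values must lie in [0, primer_length]")
  }
  rows <- lapply(sort(unique(as.integer(hd_values))), function(hd) {
    withr::with_seed(derive_seed(config$rng_seed, paste0("hyb-hd-", hd)), {
      primers <- .generate_primers(config$n_trials, config$primer_length,
                                   config$gc_range, config$tm_range,
                                   config$max_homopolymer)
      mutants <- if (hd == 0) primers else
        vapply(primers, function(p)
          .Call(`_dnapreview_mutate_walk`, p, hd, 1000000L),
          character(1), USE.NAMES = FALSE)
      ed <- .Call(`_dnapreview_levenshtein_pairwise`, primers, mutants,
                  config$primer_length)
      keep <- ed > hd - config$edit_screen_margin
      n_kept <- sum(keep)
      if (n_kept == 0) {
        warn(sprintf("all %d trials screened out at HD %d; entry reported as missing",
                     config$n_trials, hd))
        return(tibble(hd = hd, n_trials = config$n_trials, n_kept = 0L,
                      n_bound = NA_integer_, fraction_bound = NA_real_))
      }
      dg <- duplex_dG(primers[keep], revcomp(mutants[keep]),
                      temperature = config$eval_temperature,
                      monovalent = config$monovalent,
                      divalent = config$divalent)
      n_bound <- sum(dg < config$dG_threshold)
      tibble(hd = hd, n_trials = config$n_trials, n_kept = n_kept,
             n_bound = as.integer(n_bound),
             fraction_bound = n_bound / n_kept)
    })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("hyb_curve", class(out))
  attr(out, "config") <- config
  out
}
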