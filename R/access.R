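# Stringent-to-promiscuous PCR access simulation: equilibrium primer
# binding, competitive cycle-by-cycle amplification with primer depletion,
# and error-prone background generation with GB-scale accounting.

# Phenomenological per-mismatch free-energy penalty (kcal/mol) under a PCR
# condition. KCl increases specificity (larger penalty); MgCl2 increases
# promiscuity (smaller penalty). Calibrated so the 0/2/4/6 HD access
# thresholds fall inside the screened 40-60 C window.
.MM_PEN_BASE <- 1.5
.MM_PEN_KCL <- 0.4 / 50 # per mM KCl above 50
.MM_PEN_MG <- 0.3       # per mM MgCl2 above 2

mismatch_penalty <- function(kcl = 50, mgcl2 = 2) {
  max(0.05, .MM_PEN_BASE + .MM_PEN_KCL * (kcl - 50) - .MM_PEN_MG * (mgcl2 - 2))
}

#' A PCR condition
#'
#' @param annealing_temperature degrees C, in \[30, 75\].
#' @param primer_concentration per-primer concentration, nM.
#' @param mgcl2,kcl salt concentrations, mM. Amplification is completely
#'   inhibited above 150 mM KCl.
#' @param cycles PCR cycles (default 35).
#' @param polymerase_efficiency per-event extension efficiency in (0, 1\].
#' @param label optional condition name.
#' @return one-row tibble of class `pcr_condition`.
#' @export
pcr_condition <- function(annealing_temperature, primer_concentration,
                          mgcl2 = 2, kcl = 50, cycles = 35L,
                          polymerase_efficiency = 0.95, label = NA_character_) {
  if (annealing_temperature < 30 || annealing_temperature > 75) {
    abort("annealing_temperature must lie in [30, 75] C")
  }
  if (primer_concentration < 0 || mgcl2 < 0 || kcl < 0) {
    abort("concentrations must be non-negative")
  }
  stopifnot(polymerase_efficiency > 0, polymerase_efficiency <= 1)
  out <- tibble(label = label,
                annealing_temperature = annealing_temperature,
                primer_concentration = primer_concentration,
                mgcl2 = mgcl2, kcl = kcl, cycles = as.integer(cycles),
                polymerase_efficiency = polymerase_efficiency)
  class(out) <- c("pcr_condition", class(out))
  out
}

#' Equilibrium fraction of binding sites occupied by primer
#'
#' Primer-excess two-state binding: `theta = cK / (1 + cK)` with
#' `K = exp(-dG / (R T))` and the primer concentration `c` in mol/L.
#'
#' @param dG duplex free energy, kcal/mol.
#' @param temperature_K absolute temperature, K.
#' @param primer_conc primer concentration, nM.
#' @return fraction bound in \[0, 1\]. Vectorized over all arguments.
#' @export
binding_theta <- function(dG, temperature_K, primer_conc) {
  stopifnot(all(temperature_K > 0), all(primer_conc >= 0))
  ck <- (primer_conc * 1e-9) * exp(-dG / (R_GAS * temperature_K))
  ck / (1 + ck)
}

# Free primer concentration under competitive equilibrium: solve
# c_free + sum(N_i * theta_i(c_free)) = c_total for c_free (all nM).
.free_primer <- function(c_total, N, K) {
  if (c_total <= 0) return(0)
  f <- function(cf) cf + sum(N * (cf * 1e-9 * K) / (1 + cf * 1e-9 * K)) - c_total
  stats::uniroot(f, c(0, c_total), tol = max(1e-12 * c_total, 1e-15))$root
}

# Core competitive amplification over species defined by per-site duplex
# free energies. dG_fwd/dG_rev are the perfect-match energies plus mismatch
# penalties at the condition temperature. Returns the abundance trajectory.
.amplify <- function(copies, dG_fwd, dG_rev, condition) {
  cond <- as.list(condition[1, ])
  tk <- cond$annealing_temperature + 273.15
  eff <- if (cond$kcl > 150) 0 else cond$polymerase_efficiency
  Kf <- exp(-dG_fwd / (R_GAS * tk))
  Kr <- exp(-dG_rev / (R_GAS * tk))
  N <- copies
  Pf <- Pr <- cond$primer_concentration
  traj <- matrix(0, cond$cycles + 1L, length(N))
  traj[1, ] <- N
  for (cy in seq_len(cond$cycles)) {
    cff <- .free_primer(Pf, N, Kf)
    cfr <- .free_primer(Pr, N, Kr)
    thf <- (cff * 1e-9 * Kf) / (1 + cff * 1e-9 * Kf)
    thr <- (cfr * 1e-9 * Kr) / (1 + cfr * 1e-9 * Kr)
    new <- N * eff * thf * thr
    demand <- sum(new)
    avail <- min(Pf, Pr)
    if (demand > avail) new <- new * (avail / demand)
    N <- N + new
    Pf <- Pf - sum(new)
    Pr <- Pr - sum(new)
    traj[cy + 1L, ] <- N
  }
  list(final = N, trajectory = traj, primer_left = c(fwd = Pf, rev = Pr))
}

# perfect-match duplex free energy of a primer at condition temperature/salt
.pm_dG <- function(primer, condition) {
  duplex_dG(primer, revcomp(primer),
            temperature = condition$annealing_temperature[1],
            monovalent = condition$kcl[1], divalent = condition$mgcl2[1])
}

#' Simulate a competitive PCR over template species
#'
#' Each cycle the free primer concentration partitions over all binding
#' sites at equilibrium, each species grows by
#' `1 + efficiency * theta_fwd * theta_rev`, and consumed primers are
#' subtracted (amplification stalls as primers exhaust; higher-HD species
#' stall first as the falling free-primer concentration raises effective
#' stringency). Mismatched sites use the perfect-match free energy plus the
#' condition-dependent per-mismatch penalty.
#'
#' @param species tibble with columns `label`, `hd_fwd`, `hd_rev`, `copies`
#'   (initial concentration, nM) and optionally `length_bp`.
#' @param condition a [pcr_condition()].
#' @param primer_fwd,primer_rev accessing primer sequences (reverse defaults
#'   to forward's thermodynamics).
#' @param detection_ratio nonspecific:specific ratio above which a
#'   nonspecific species counts as amplified/visible (default 0.01).
#' @return list of class `pcr_amplification`: `species` (with `final`,
#'   `gain`, `product_fraction`), `trajectory` (long tibble), `condition`,
#'   `detection_ratio`.
#' @export
simulate_competitive_pcr <- function(species, condition, primer_fwd,
                                     primer_rev = primer_fwd,
                                     detection_ratio = 0.01) {
  stopifnot(nrow(species) >= 1)
  if (is.data.frame(primer_fwd)) primer_fwd <- primer_fwd$seq[1]
  if (is.data.frame(primer_rev)) primer_rev <- primer_rev$seq[1]
  pen <- mismatch_penalty(condition$kcl[1], condition$mgcl2[1])
  dgf <- .pm_dG(primer_fwd, condition) + pen * species$hd_fwd
  dgr <- .pm_dG(primer_rev, condition) + pen * species$hd_rev
  amp <- .amplify(species$copies, dgf, dgr, condition)
  out <- species
  out$final <- amp$final
  out$gain <- amp$final / species$copies
  prod <- amp$final - species$copies
  out$product_fraction <- if (sum(prod) > 0) prod / sum(prod) else 0
  traj <- tibble(
    cycle = rep(0:condition$cycles[1], times = nrow(species)),
    label = rep(species$label, each = condition$cycles[1] + 1L),
    abundance = as.vector(amp$trajectory))
  structure(list(species = out, trajectory = traj, condition = condition,
                 detection_ratio = detection_ratio,
                 primer_consumed = condition$primer_concentration[1] -
                   amp$primer_left,
                 synthesized = sum(amp$final - species$copies)),
            class = "pcr_amplification")
}

#' Named access conditions anchored to the model's thermodynamics
#'
#' Returns the three default File Preview access conditions. Each condition's
#' annealing temperature is solved from the model itself: the temperature at
#' which the binding constant of the target tier satisfies
#' `K = 1 / (gamma * P)` (i.e. the tier's amplification stalls once the free
#' primer falls to a fraction `gamma` of the budget `P`). Anchoring to the
#' model rather than to fixed temperatures makes tier behavior independent
#' of the particular primer sequence:
#'
#' * `preview` (most stringent): tier 0 anchored, 250 nM, 2 mM MgCl2 —
#'   accesses only the 0-HD Preview strands.
#' * `intermediate`: tier 4 anchored, 250 nM, 2 mM MgCl2 — accesses 0+4.
#' * `full` (promiscuous): tier 6 anchored, 1000 nM, 4 mM MgCl2 —
#'   accesses 0+4+6.
#'
#' @param primer_fwd accessing forward primer (string or tibble).
#' @param gamma stall-fraction anchors for the three conditions.
#' @return tibble of class `pcr_condition`, three rows.
#' @export
access_conditions <- function(primer_fwd,
                              gamma = c(preview = 0.12, intermediate = 0.12,
                                        full = 0.10)) {
  if (is.data.frame(primer_fwd)) primer_fwd <- primer_fwd$seq[1]
  spec <- tibble(label = c("preview", "intermediate", "full"),
                 hd = c(0L, 4L, 6L),
                 primer_concentration = c(250, 250, 1000),
                 mgcl2 = c(2, 2, 4), kcl = 50,
                 gamma = unname(gamma))
  solve_T <- function(hd, P, mg, kcl, gm) {
    pen <- mismatch_penalty(kcl, mg)
    f <- function(tc) {
      dg <- duplex_dG(primer_fwd, revcomp(primer_fwd), temperature = tc,
                      monovalent = kcl, divalent = mg) + pen * hd
      exp(-dg / (R_GAS * (tc + 273.15))) - 1 / (gm * P * 1e-9)
    }
    stats::uniroot(f, c(20, 95))$root
  }
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    s <- spec[i, ]
    tc <- solve_T(s$hd, s$primer_concentration, s$mgcl2, s$kcl, s$gamma)
    pcr_condition(min(75, max(30, tc)), s$primer_concentration,
                  mgcl2 = s$mgcl2, kcl = s$kcl, label = s$label)
  })
  dplyr::bind_rows(rows)
}

#' Simulate PCR access over an encoded strand library
#'
#' Tier-level competitive amplification: strands sharing an HD tier form one
#' species whose initial concentration is the per-strand concentration times
#' the summed stored copies. A tier is *accessed* when its fold
#' amplification reaches `min_fold` (an amplified product is what a gel or a
#' sequencing library preparation sees; unamplified stored material is
#' diluted out).
#'
#' @param library a `preview_library` from [encode_file()], or its `strands`
#'   tibble (needs `id`, `hd_tier`, `copies`).
#' @param condition a [pcr_condition()] (one of [access_conditions()]).
#' @param manifest manifest carrying the base address pair; required when
#'   `library` is a bare tibble.
#' @param per_strand_nM initial concentration of a single stored copy
#'   (default 1e-9 nM).
#' @param min_fold fold-amplification readout threshold (default 10).
#' @return list of class `access_result`: `tiers` (hd_tier, copies, initial,
#'   final, gain, accessed), `strands` (id, hd_tier, abundance),
#'   `accessed_tiers`, `condition`.
#' @export
simulate_access <- function(library, condition, manifest = NULL,
                            per_strand_nM = 1e-9, min_fold = 10) {
  if (inherits(library, "preview_library")) {
    manifest <- library$manifest
    strands <- library$strands
  } else strands <- library
  if (is.null(manifest)) abort("manifest required to locate the base address pair")
  tiers <- strands |>
    dplyr::group_by(.data$hd_tier) |>
    dplyr::summarise(copies_total = sum(.data$copies), n_strands = dplyr::n(),
                     .groups = "drop")
  species <- tibble(label = paste0("tier", tiers$hd_tier),
                    hd_fwd = tiers$hd_tier, hd_rev = tiers$hd_tier,
                    copies = per_strand_nM * tiers$copies_total)
  amp <- simulate_competitive_pcr(species, condition,
                                  primer_fwd = manifest$base_fwd,
                                  primer_rev = manifest$base_rev)
  tiers$initial <- amp$species$copies
  tiers$final <- amp$species$final
  tiers$gain <- amp$species$gain
  tiers$accessed <- tiers$gain >= min_fold
  per_strand <- strands |>
    dplyr::left_join(tiers[, c("hd_tier", "final", "copies_total")],
                     by = "hd_tier") |>
    dplyr::mutate(abundance = .data$final * .data$copies / .data$copies_total) |>
    dplyr::select(dplyr::all_of(c("id", "partition", "hd_tier", "abundance")))
  structure(list(tiers = tiers, strands = per_strand,
                 accessed_tiers = tiers$hd_tier[tiers$accessed],
                 condition = condition, trajectory = amp$trajectory),
            class = "access_result")
}

#' Error-prone PCR substitution profile
#'
#' Per-cycle 4x4 row-stochastic substitution matrix. The default is
#' transition-biased (A<->G and C<->T elevated `transition_bias`-fold over
#' each transversion), reflecting dPTP / 8-oxo-dGTP mutagenesis chemistry.
#'
#' @param rate total substitution probability per base per cycle.
#' @param transition_bias transition:transversion rate ratio (default 10).
#' @param cycles number of mutagenic cycles (default 35).
#' @return list of class `error_prone_profile` with `matrix` and `cycles`.
#' @export
error_prone_profile <- function(rate = 2e-3, transition_bias = 10,
                                cycles = 35L) {
  stopifnot(rate >= 0, rate < 0.5, transition_bias > 0)
  tv <- rate / (transition_bias + 2)
  ti <- transition_bias * tv
  m <- matrix(tv, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  diag(m) <- 0
  m["A", "G"] <- m["G", "A"] <- m["C", "T"] <- m["T", "C"] <- ti
  diag(m) <- 1 - rowSums(m)
  stopifnot(all(abs(rowSums(m) - 1) < 1e-12), all(diag(m) >= m[!diag(4)]))
  structure(list(matrix = m, rate = rate, cycles = as.integer(cycles)),
            class = "error_prone_profile")
}

#' Generate an error-prone PCR background pool
#'
#' Produces `n_unique` mutagenized copies of `template`, each passed through
#' `profile$cycles` rounds of independent per-base substitution sampling.
#' Emulates the randomized nonspecific background surrounding a target file
#' in a large store.
#'
#' @param template DNA string.
#' @param n_unique number of background strands.
#' @param profile an [error_prone_profile()].
#' @param seed optional integer seed.
#' @return tibble with columns `id`, `seq`.
#' @export
error_prone_background <- function(template, n_unique,
                                   profile = error_prone_profile(),
                                   seed = NULL) {
  .check_dna(template, "template")
  stopifnot(n_unique >= 1)
  run <- function() {
    L <- nchar(template)
    m <- matrix(rep(match(seq_chars(template)[[1]], DNA_BASES), n_unique),
                nrow = n_unique, byrow = TRUE)
    off_p <- 1 - diag(profile$matrix) # per-base mutation prob given current
    for (cy in seq_len(profile$cycles)) {
      hit <- which(stats::runif(length(m)) < off_p[m])
      if (!length(hit)) next
      cur <- m[hit]
      # conditional target distribution given mutation occurs
      u <- stats::runif(length(hit))
      newb <- integer(length(hit))
      for (b in 1:4) {
        sel <- cur == b
        if (!any(sel)) next
        probs <- profile$matrix[b, ]
        probs[b] <- 0
        probs <- probs / sum(probs)
        cp <- cumsum(probs)
        newb[sel] <- findInterval(u[sel], cp, left.open = TRUE) + 1L
      }
      m[hit] <- newb
    }
    tibble(id = sprintf("bg_%06d", seq_len(n_unique)),
           seq = apply(matrix(DNA_BASES[m], nrow = n_unique), 1,
                       paste, collapse = ""))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Background accounting layout
#'
#' Byte bookkeeping of a single-primer-pair background strand: 200 nt minus
#' two 20-nt primers, a 16-nt index and an 8-nt checksum leaves 136 nt, i.e.
#' 17 one-byte codewords of 8 nt.
#'
#' @param strand_nt,primer_nt,index_nt,checksum_nt,codeword_nt layout, nt.
#' @param redundancy assumed physical copies per unique strand (default 10).
#' @return list of class `background_accounting` with `bytes_per_strand`.
#' @export
background_accounting <- function(strand_nt = 200L, primer_nt = 20L,
                                  index_nt = 16L, checksum_nt = 8L,
                                  codeword_nt = 8L, redundancy = 10) {
  bps <- (strand_nt - 2L * primer_nt - index_nt - checksum_nt) / codeword_nt
  structure(list(strand_nt = strand_nt, primer_nt = primer_nt,
                 index_nt = index_nt, checksum_nt = checksum_nt,
                 codeword_nt = codeword_nt, bytes_per_strand = bps,
                 redundancy = redundancy),
            class = "background_accounting")
}

#' Data quantity represented by a physical background pool
#'
#' `GB = n_physical_strands * bytes_per_strand / redundancy / 1e9`.
#'
#' @param n_physical_strands total physical strand count.
#' @param acct a [background_accounting()].
#' @return gigabytes (numeric).
#' @export
background_gb <- function(n_physical_strands, acct = background_accounting()) {
  stopifnot(n_physical_strands >= 0)
  n_physical_strands * acct$bytes_per_strand / acct$redundancy / 1e9
}
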