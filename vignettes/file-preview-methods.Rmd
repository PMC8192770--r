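---
title: "Tiered File Preview for DNA data storage: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiered File Preview for DNA data storage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnapreview)
```

## The problem

PCR-addressed DNA storage retrieves a file by amplifying the strands that
carry its 20-nt address sequences. Address-primer hybridization is
thermodynamic, not all-or-none: a primer still binds sites that differ from
its perfect complement by a few mismatches, with an affinity that falls off
with the Hamming distance (HD) between address variants. Conventional
designs discard all addresses within ~10 HD of each other to avoid
cross-talk. dnapreview implements the opposite strategy: it *uses* that
graded affinity. A file's strands are split into partitions tagged with
address variants at increasing HD from a single accessing primer pair
(tiers 0, 4 and 6 by default). Stringent PCR conditions (high annealing
temperature, low primer) amplify only the 0-HD tier — a low-resolution
*Preview* of the file; progressively promiscuous conditions (lower
temperature, more primer, more Mg²⁺) pull in the 4- and then 6-HD tiers,
reconstructing the file at increasing fidelity from the same primer pair.

## Duplex thermodynamics

`duplex_dG()` is a two-state nearest-neighbor model: Watson–Crick stacks use
the unified oligonucleotide dH/dS parameters; stacks containing a single
internal mismatch use the published mismatch tables (the compilation of
Allawi & SantaLucia and Peyret et al., 87 stack entries plus rotational
equivalents); stacks with no published parameters — adjacent double
mismatches — incur a fixed +1.8 kcal/mol. Salt enters through the entropic
correction `0.368 (L-1) ln[Na+_eq]` with `[Na+_eq] = [mono] + 120 sqrt([div])`
(mM). `nn_tm()` uses the same tables with the `CT/4` two-state formula at a
50 mM monovalent reference — the convention under which the 50–55 °C primer
design window is expressed.

Defaults for free-energy evaluation are 37 °C and 1 M monovalent — the
reference conditions of standard secondary-structure software, chosen once
before any calibration. Absolute ΔG values are *not* a claim of this
package; curve shape is.

`hybridization_curve()` is the Monte-Carlo front end: for each HD it draws
fresh constraint-satisfying primers (GC 40–60%, Tm 50–55 °C, homopolymer
≤ 4), mutates each to the exact HD by a repeat-until substitution walk,
screens out trials whose edit distance falls to `hd - 3` or below (shifted
near-duplicates that bind despite high HD), and classifies binding as
duplex ΔG below −10 kcal/mol. With these choices the curve is 1.0 at HD 0,
declines through HD 2–6 and is indistinguishable from zero by HD 8–10 —
the "waste" address space the tiered design then exploits. The edit-screen
margin of 3 removes shift artifacts while discarding almost no
substitution-walk mutants (they are rare by construction).

## Competitive PCR access

Each cycle, every template species competes for the same primer pool. The
free primer concentration `c` partitions over all binding sites at
equilibrium (solving `c + Σ N_i θ_i(c) = c_total`, with
`θ = cK/(1+cK)`, `K = exp(-ΔG/RT)`), each species then grows by
`1 + ε θ_fwd θ_rev`, and the synthesized strands consume primers
one-for-one (mass balance holds exactly). This produces the essential
stringency cascade: as primers deplete, the falling free concentration
raises effective stringency, so high-HD tiers stall first while the 0-HD
tier keeps amplifying — which is how the stored-copy imbalance
(1×/100×/1000×) evens out into comparable sequencing coverage per tier.

Mismatched sites use the perfect-match ΔG plus a phenomenological
per-mismatch penalty:

* base 1.5 kcal/mol per mismatch (50 mM KCl, 2 mM MgCl₂);
* +0.4 kcal/mol per mismatch per 50 mM KCl above 50 (KCl raises
  specificity, up to complete inhibition above 150 mM);
* −0.3 kcal/mol per mismatch per mM MgCl₂ above 2 (Mg²⁺ raises
  promiscuity).

These are signed, directional calibrations, not electrostatic mechanics;
they place the 0→2→4→6 HD access thresholds inside the screened 40–60 °C
window and reproduce the observed signs of the salt effects. The published
single-mismatch NN tables are deliberately *not* used here: tier access
operates on (tier, penalty) abstractions so that behavior depends only on
the declared HD, not on which particular variant the walk produced.

`access_conditions()` defines the three named conditions by anchoring each
annealing temperature to the model itself: the temperature at which the
target tier's binding constant satisfies `K = 1/(γP)` — i.e. that tier's
amplification stalls once free primer falls to the fraction γ of the budget
P. Preview anchors tier 0 (γ = 0.12, 250 nM, 2 mM Mg²⁺), intermediate
anchors tier 4 (γ = 0.12, 250 nM), full access anchors tier 6 (γ = 0.10,
1000 nM, 4 mM Mg²⁺). Anchoring makes tier behavior independent of the
particular primer sequence, so any library built by `encode_file()` shows
the same {0} / {0,4} / {0,4,6} access pattern.

A tier counts as *accessed* when its fold amplification reaches 10
(`min_fold`). A fraction-of-final-molecules readout is unusable under the
copy schedule: an amplified 0-HD tier can be a million-fold amplified yet
<1% of molecules next to the 1000× stored 6-HD tier, and the accessed set
would non-physically shrink as conditions grow more promiscuous. Fold
amplification is what distinguishes product from stored material and keeps
the accessed set monotone. For the two-species competitive assay (perfect
match vs 2-HD, the gel experiment's layout) the detection proxy is instead
the nonspecific:specific ratio of final concentrations, with 1% standing in
for band visibility.

## Codec

A progressive JPEG delivers its image in scans (DC averages first, then
AC frequency bands). `build_scan_script()` records the canonical 42-scan
spectral-selection order; `segment_progressive_jpeg()` splits any
progressive stream losslessly at scan boundaries (byte/marker level only —
re-concatenation is the identity). Scans group into partitions: partition 1
carries the header plus the first scans (≤ one RS block, so a Preview
access is one block), later partitions carry the rest, at strictly
increasing HD tiers with the 1×/100×/1000× copy schedule.

Each partition is protected independently:

* bytes are zero-padded to blocks of 1665 = 185 rows × 9 columns;
* an outer [255, 185, 71] Reed–Solomon code over GF(256) extends each
  column, tolerating up to 70 lost strands per block (erasure decoding);
* each row gets a 2-byte index (unique within its partition) and an inner
  [14, 11, 4] code correcting one byte error per strand;
* the 14 bytes map to 8-nt codewords from a greedy GC-balanced codebook
  (256 words, pairwise edit distance ≥ 2, deterministic construction
  identified by an MD5 hash carried in the manifest);
* an 8-nt restriction site (a distinct one per tier) sits between
  codewords 7 and 8; 20-nt tier addresses and 20-nt flanking primers
  complete the 200-nt strand.

After assembly, every 20-nt payload window is checked to sit ≥ 6 HD from
every address (both orientations). Violations are cured by redrawing the
offending tier's address pair (the base pair is itself drawn under the
guard), rather than by re-encoding payload bytes: the strand geometry
(4×20 + 14×8 + 8 = 200 nt) is exact and byte-stuffing would break it. The
guard threshold of 6 (rather than a stricter 8) keeps address redraws cheap
at desk scale while still excluding the ≤5-HD payload accidents that
motivated it.

Decoding reverses the pipeline and fails *at partition boundaries*: rows
recovered per partition (deduplicated by index with majority vote,
inner-corrected, erasure-decoded column-wise) either reconstruct the
partition or mark it failed; the JPEG is reassembled from the successful
prefix plus the end-of-image marker. Losing trailing partitions only
lowers resolution; losing partition 1 is an unreadable-image error.

## Read clustering

`cluster_reads()` re-implements the seeded message-passing scheme used for
decoding: the pool is the reads plus 20 pseudo-copies of every library
strand, unique sequences are processed in descending multiplicity (ties
lexicographic), and a sequence joins an existing centroid within 8 edits
whose count is ≥ 5× its own; otherwise it founds a centroid. Reference
centroids report their cluster size minus the 20 seeds. Candidate centroids
come from an inverted index of disjoint 12-mers — a read within 8 edits of
a 200-nt centroid must contain one of its disjoint 12-mers intact
(pigeonhole), so recall is exact. Two engineering details keep it fast on
read sets of 10⁵⁺: ubiquitous k-mers (shared primer regions, repeated
zero-padding codewords) stop indexing new centroids once 48 carry them
(the per-centroid tally counts only indexed k-mers, preserving the
pigeonhole bound), and verification proceeds in decreasing shared-k-mer
order with an early stop once a ≤2-edit hit is found. Ties between equally
distant centroids go to the larger cluster, then lexicographically. Reads
outside 150–250 nt are filtered as truncated products before clustering.

## Fixtures and what the tests show

`make_progressive_jpeg()` renders deterministic gradient / checkerboard /
noise images and encodes them progressively through the system Python's
Pillow (a fixtures-only dependency; the codec never reads pixels).
`make_noisy_reads()` Poisson-samples read counts proportional to post-PCR
abundance (mean `depth` per strand) and applies per-base errors, 10% of
them single-base indels. `error_prone_background()` emulates the
mutagenized nonspecific background (transition-biased 10:1, 2×10⁻³ per base
per cycle over 35 cycles — the reagent chemistry fixes the bias direction,
not the absolute rate, which is a chosen default).

The end-to-end study configuration is a 224×224 synthetic noise image
(~31 kB, 20 RS blocks, ~5100 strands) whose first partition holds ~5% of
unique strands, exercised at depth 30 with 1% per-base error and a
10,000-strand background. These sizes were chosen as a faithful desk-scale
replica of the method's balance (a 5% Preview share, copy schedule
1×/100×/1000×). What passing tests show: the *mechanism* — tiered access,
two-level erasure coding, clustering-based recovery, partition-boundary
degradation — is correct end to end under calibrated, idealized noise.
What they do not show: performance on real sequencer error profiles
(quality-dependent, context-dependent errors), real synthesis defects, or
thermodynamics beyond the two-state model (no secondary structure,
no multi-strand complexes).

## Economics

With a fraction *f* of unique strands as Preview strands (single copy) and
the rest at *c* copies, physical density relative to single-copy encoding
is `D = f + (1-f)c` (`density_ratio()`; the variant counting only
full-file copies is exposed as `model = "fullonly"`). Finding one file among
*n* similar files costs `n` full-file sequencings without Preview and
`n·f + 1` with it (`cost_to_find()`, search-all convention; an
expected-position variant replaces `n` by `(n+1)/2`). At `f = 0.05`,
`n = 15` the transparent model gives savings of `1 - 1.75/15 ≈ 88.3%`;
published figures derived from empirical read-depth calibrations differ by
a few points, and `cost_to_find(overhead = ...)` exposes the multiplier a
user would calibrate from their own read distributions.

## Numerical choices and limitations

* GF(256) uses the 0x11d primitive polynomial, generator α = 2, fcr = 0;
  erasure decoding is syndrome-based (Forney), errors via Berlekamp–Massey.
  Decoding failure is detected by re-checking syndromes; a block with more
  than 70 missing rows is reported failed, never silently wrong.
* All per-module randomness derives named child seeds from one top-level
  seed, so primer design, mutation walks, backgrounds and read simulation
  are independently reproducible.
* The equilibrium free-primer solve uses monotone root-finding per cycle;
  35 cycles per condition, exact mass balance.
* The repeat-until mutation walk can revisit positions; its iteration cap
  (10⁶) is unreachable for any feasible target and exists only to convert
  a hypothetical infinite loop into an error.
* `encode_file()` requires progressive input by design; baseline JPEG is a
  typed error, not a silent fallback. Arbitrary byte payloads can still be
  protected via `encode_partition()`/`decode_strands()` — scan-aware
  previewing is what is JPEG-specific.
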