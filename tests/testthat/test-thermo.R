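test_that("hamming_distance counts substitutions and enforces equal lengths", {
  expect_identical(hamming_distance("ACGT", "ACGT"), 0L)
  expect_identical(hamming_distance("ACGT", "ACGA"), 1L)
  a <- strrep("A", 20)
  b <- strrep("C", 20)
  expect_identical(hamming_distance(a, b), 20L)
  expect_identical(hamming_distance(a, b), hamming_distance(b, a))
  expect_error(hamming_distance("ACGT", "ACG"), "equal lengths")
})

test_that("edit_distance is the unit-cost Levenshtein distance", {
  expect_identical(edit_distance("ACGT", "ACGT"), 0L)
  # one-position circular shift: expected value from the textbook DP recursion
  dp_lev <- function(a, b) {
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    d <- matrix(0L, length(av) + 1, length(bv) + 1)
    d[, 1] <- 0:length(av); d[1, ] <- 0:length(bv)
    for (i in seq_along(av)) for (j in seq_along(bv)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (av[i] != bv[j]))
    }
    d[length(av) + 1, length(bv) + 1]
  }
  expect_identical(dp_lev("AACCGGTT", "ACCGGTTA"), 2L)
  expect_identical(edit_distance("AACCGGTT", "ACCGGTTA"), 2L)
  expect_identical(edit_distance("A", ""), 1L)
  # the banded C++ kernel agrees with the DP oracle on random pairs
  set.seed(5)
  for (i in 1:25) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(5:15, 1), TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(5:15, 1), TRUE), collapse = "")
    truth <- dp_lev(a, b)
    got <- dnapreview:::levenshtein_bounded(a, b, 20L)
    expect_identical(got, as.integer(truth))
  }
})

test_that("design_random_primer satisfies constraints and is seed-reproducible", {
  p <- design_random_primer(20, c(0.40, 0.60), c(50, 55), 4, seed = 1)
  expect_identical(nchar(p$seq), 20L)
  expect_gte(p$gc_fraction, 0.40)
  expect_lte(p$gc_fraction, 0.60)
  expect_gte(p$tm, 50)
  expect_lte(p$tm, 55)
  expect_lte(max(rle(strsplit(p$seq, "")[[1]])$lengths), 4)
  expect_identical(p, design_random_primer(20, c(0.40, 0.60), c(50, 55), 4, seed = 1))
  # all-GC primers melt far above the 50-55 window: infeasible
  expect_error(
    design_random_primer(20, c(0.99, 1.0), c(50, 55), 20, seed = 1,
                         max_attempts = 20000),
    class = "dnapreview_generation_failure")
})

test_that("mutate_to_hd reaches the exact target distance", {
  p <- design_random_primer(seed = 2)
  expect_identical(mutate_to_hd(p, 0), p$seq)
  m <- mutate_to_hd(p, 2, seed = 7)
  expect_identical(hamming_distance(p$seq, m), 2L)
  m20 <- mutate_to_hd(p, 20, seed = 7)
  expect_identical(hamming_distance(p$seq, m20), 20L)
  expect_error(mutate_to_hd(p, 21), "target_hd")
  # hard assertion over many trials at HD 2
  withr::with_seed(99, {
    hds <- replicate(10000, hamming_distance(p$seq, mutate_to_hd(p$seq, 2)))
  })
  expect_true(all(hds == 2L))
})

test_that("duplex_dG matches hand-summed nearest-neighbor arithmetic", {
  # independent summation: explicit dH/dS stack terms + initiation + salt,
  # written out against the published unified parameter table
  hand_dG <- function(seq, temp_c = 37, mono = 1000) {
    dh_tab <- c(AA = -7.9, AT = -7.2, AG = -7.8, AC = -8.4,
                TA = -7.2, TT = -7.9, TG = -8.5, TC = -8.2,
                CA = -8.5, CT = -7.8, CG = -10.6, CC = -8.0,
                GA = -8.2, GT = -8.4, GG = -8.0, GC = -9.8)
    ds_tab <- c(AA = -22.2, AT = -20.4, AG = -21.0, AC = -22.4,
                TA = -21.3, TT = -22.2, TG = -22.7, TC = -22.2,
                CA = -22.7, CT = -21.0, CG = -27.2, CC = -19.9,
                GA = -22.2, GT = -22.4, GG = -19.9, GC = -24.4)
    v <- strsplit(seq, "")[[1]]
    L <- length(v)
    ks <- paste0(v[-L], v[-1])
    dh <- sum(dh_tab[ks]); ds <- sum(ds_tab[ks])
    for (e in c(1, L)) {
      if (v[e] %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
      else { dh <- dh + 2.3; ds <- ds + 4.1 }
    }
    ds <- ds + 0.368 * (L - 1) * log(mono / 1000)
    dh - (temp_c + 273.15) * ds / 1000
  }
  for (s in c("ACTGGTCAAGTCTAGCATGC", "GATTACAGATTACAGATTAC",
              "CCGGTTAACCGGTTAACCGG")) {
    expect_equal(duplex_dG(s, revcomp(s)), hand_dG(s), tolerance = 1e-9)
  }
  # symmetry of the duplex orientation convention
  a <- "ACTGGTCAAGTCTAGCATGC"; b <- revcomp(a)
  expect_equal(duplex_dG(a, b), duplex_dG(b, a), tolerance = 1e-12)
  # a non-self-complementary strand paired with itself is destabilized
  expect_gt(duplex_dG(a, a), duplex_dG(a, revcomp(a)))
  # longer perfect duplex is more stable at fixed composition
  expect_lt(duplex_dG(strrep("AC", 10), revcomp(strrep("AC", 10))),
            duplex_dG(strrep("AC", 5), revcomp(strrep("AC", 5))))
  expect_error(duplex_dG("A", "T"), "at least 2 nt")
})

test_that("hybridization_curve: perfect match always binds; deterministic under seed", {
  cfg <- hyb_config(n_trials = 100L, rng_seed = 42L)
  cv <- hybridization_curve(c(0, 4, 12), cfg)
  expect_identical(cv$fraction_bound[cv$hd == 0], 1)
  expect_true(all(cv$fraction_bound >= 0 & cv$fraction_bound <= 1))
  cv2 <- hybridization_curve(c(0, 4, 12), cfg)
  expect_identical(cv$fraction_bound, cv2$fraction_bound)
  # subsets reproduce: per-HD streams are independent
  cv3 <- hybridization_curve(4, cfg)
  expect_identical(cv3$fraction_bound, cv$fraction_bound[cv$hd == 4])
  td <- tidy(cv)
  expect_identical(nrow(td), 3L)
  expect_true(all(c("fraction_bound", "se") %in% names(td)))
})
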