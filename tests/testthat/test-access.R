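test_that("binding_theta has the right limits and monotonicity", {
  expect_identical(binding_theta(-15, 330, 0), 0)
  expect_equal(binding_theta(-200, 330, 250), 1, tolerance = 1e-12)
  th <- binding_theta(-12, 328, c(10, 100, 1000))
  expect_true(all(diff(th) > 0))
  th2 <- binding_theta(c(-14, -12, -10), 328, 250)
  expect_true(all(diff(th2) < 0))
})

test_that("competitive PCR amplifies, balances mass and preserves equal-dG ratios", {
  p <- design_random_primer(seed = 41)$seq
  cond <- pcr_condition(55, 250)
  one <- simulate_competitive_pcr(
    tibble::tibble(label = "pm", hd_fwd = 0, hd_rev = 0, copies = 1e-4),
    cond, p)
  expect_gt(one$species$final, one$species$copies)
  # mass balance: primers consumed == strands synthesized
  expect_equal(unname(one$primer_consumed["fwd"]), one$synthesized,
               tolerance = 1e-9)
  expect_equal(unname(one$primer_consumed["rev"]), one$synthesized,
               tolerance = 1e-9)
  # equal dG for all species => final ratios equal initial copy ratios
  sp <- tibble::tibble(label = c("a", "b", "c"), hd_fwd = 2, hd_rev = 2,
                       copies = c(1e-5, 3e-5, 6e-5))
  res <- simulate_competitive_pcr(sp, pcr_condition(50, 250), p)
  expect_equal(res$species$final / res$species$final[1],
               sp$copies / sp$copies[1], tolerance = 1e-9)
  # abundances never decrease over cycles
  expect_true(all(dplyr::arrange(res$trajectory, label, cycle) |>
                    dplyr::group_by(label) |>
                    dplyr::summarise(mono = all(diff(abundance) >= -1e-12)) |>
                    dplyr::pull(mono)))
})

test_that("stringency directionality: temperature, primer, MgCl2, KCl", {
  p <- design_random_primer(seed = 42)$seq
  sp <- tibble::tibble(label = c("s", "ns"), hd_fwd = c(0, 2),
                       hd_rev = c(0, 2), copies = 2.77e-4)
  # directional behavior is asserted on the detectable amplified product:
  # the mismatch share of synthesized strands, clamped at the 1% detection
  # proxy (below detection, ordering carries no information)
  ns_frac <- function(cond) {
    r <- simulate_competitive_pcr(sp, cond, p)
    max(r$species$product_fraction[2], 0.01)
  }
  # mismatch fraction decreases with annealing temperature
  fr_t <- vapply(c(45, 50, 55, 60), function(tc)
    ns_frac(pcr_condition(tc, 250)), numeric(1))
  expect_true(all(diff(fr_t) <= 1e-12))
  # increases with primer concentration at fixed temperature
  fr_c <- vapply(c(125, 250, 500, 1000), function(cc)
    ns_frac(pcr_condition(53, cc)), numeric(1))
  expect_true(all(diff(fr_c) >= -1e-12))
  # increases with MgCl2
  fr_mg <- vapply(c(1, 2, 3), function(mg)
    ns_frac(pcr_condition(53, 250, mgcl2 = mg)), numeric(1))
  expect_true(all(diff(fr_mg) >= -1e-12))
  # decreases with KCl up to 150 mM; amplification is abolished beyond
  fr_k <- vapply(c(50, 100, 150), function(k)
    ns_frac(pcr_condition(50, 250, kcl = k)), numeric(1))
  expect_true(all(diff(fr_k) <= 1e-12))
  dead <- simulate_competitive_pcr(sp, pcr_condition(50, 250, kcl = 200), p)
  expect_equal(dead$species$final, dead$species$copies, tolerance = 1e-12)
})

test_that("error-prone background matches the closed-form mutation expectation", {
  prof <- error_prone_profile(rate = 2e-3, cycles = 35)
  expect_equal(unname(rowSums(prof$matrix)), rep(1, 4), tolerance = 1e-12)
  expect_true(all(diag(prof$matrix) > apply(prof$matrix, 1, function(r) max(r[-which.max(r)]))))
  tmpl <- paste(rep(c("A", "C", "G", "T"), 50), collapse = "")
  # identity profile: all copies equal the template
  id_prof <- error_prone_profile(rate = 0)
  bg0 <- error_prone_background(tmpl, 20, id_prof, seed = 1)
  expect_true(all(bg0$seq == tmpl))
  # substitution expectation: L * (1 - (1 - r)^cycles) within 3 SE
  bg <- error_prone_background(tmpl, 1000, prof, seed = 2)
  muts <- vapply(bg$seq, function(s) hamming_distance(s, tmpl), integer(1))
  expected <- 200 * (1 - (1 - 2e-3)^35)
  se <- stats::sd(muts) / sqrt(length(muts))
  expect_lt(abs(mean(muts) - expected), 3 * se + 0.2)
  expect_identical(bg$seq, error_prone_background(tmpl, 1000, prof, seed = 2)$seq)
})

test_that("background accounting: 17 bytes per strand and GB conversion", {
  acct <- background_accounting()
  expect_identical(acct$bytes_per_strand, 17)
  expect_identical(background_gb(0), 0)
  # invert the formula: 1.5 GB corresponds to ~8.82e8 physical strands
  n <- 1.5e9 * acct$redundancy / acct$bytes_per_strand
  expect_equal(background_gb(n), 1.5, tolerance = 1e-12)
  expect_equal(n, 8.82e8, tolerance = 0.01)
})

test_that("access over the encoded library: accessed sets grow with promiscuity", {
  lib <- fx_library_small()
  conds <- access_conditions(lib$manifest$base_fwd)
  acc <- lapply(seq_len(3), function(i) simulate_access(lib, conds[i, ]))
  expect_identical(acc[[1]]$accessed_tiers, 0L)
  expect_identical(acc[[2]]$accessed_tiers, c(0L, 4L))
  expect_identical(acc[[3]]$accessed_tiers, c(0L, 4L, 6L))
  # accessed set monotone non-shrinking as temperature decreases
  sets <- lapply(seq(62, 42, by = -4), function(tc) {
    simulate_access(lib, pcr_condition(tc, 250))$accessed_tiers
  })
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  }
  gl <- glance(acc[[1]])
  expect_identical(gl$accessed_tiers, "0")
})
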