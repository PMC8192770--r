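test_that("density ratio reproduces the reference configurations", {
  expect_equal(round(density_ratio(0.05, 100)), 95)
  expect_equal(round(density_ratio(0.05, 5), 1), 4.8)
  expect_equal(round(density_ratio(0.05, 10), 1), 9.6)
  # no extra copies: density parity with normal encoding at any f
  expect_equal(density_ratio(c(0.01, 0.2, 1), 1), rep(1, 3))
  # alternative model counts full-file copies only
  expect_equal(round(density_ratio(0.05, 10, model = "fullonly"), 1), 9.5)
  expect_error(density_ratio(0, 10), "f must")
  expect_error(density_ratio(0.1, 0.5), "c must")
})

test_that("density ratio is linear in c and decreasing in f for c > 1", {
  f <- 0.3
  cs <- c(2, 4, 8, 16)
  d <- density_ratio(f, cs)
  expect_equal(diff(d) / diff(cs), rep(1 - f, 3))
  fs <- seq(0.05, 0.95, by = 0.1)
  expect_true(all(diff(density_ratio(fs, 10)) < 0))
})

test_that("cost to find: search-all arithmetic and limits", {
  r <- cost_to_find(15, 0.05)
  expect_equal(r$cost_preview, 1.75)
  expect_equal(r$cost_normal, 15)
  expect_equal(r$savings, 1 - 1.75 / 15, tolerance = 1e-12)
  # f -> 0 limit: savings approach 1 - 1/n
  r0 <- cost_to_find(15, 1e-9)
  expect_equal(r0$savings, 1 - 1 / 15, tolerance = 1e-6)
  # expected-position variant
  re <- cost_to_find(15, 0.05, search_all = FALSE)
  expect_equal(re$cost_normal, 8)
  expect_equal(re$cost_preview, 8 * 0.05 + 1)
  expect_error(cost_to_find(15, 1), "f must")
})

test_that("savings grow with library size and shrink with preview fraction", {
  s_f <- cost_to_find(15, c(0.01, 0.05, 0.1, 0.3))$savings
  expect_true(all(diff(s_f) < 0))
  s_n <- cost_to_find(c(5, 15, 50, 200), 0.05)$savings
  expect_true(all(diff(s_n) > 0))
  sw <- economics_sweep(f = c(0.01, 0.05), c = c(5, 100), n_files = 15)
  expect_identical(nrow(sw), 4L)
  expect_true(all(c("density_ratio", "savings") %in% names(sw)))
})
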