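# Storage-density and cost-to-find economics of Preview encoding.

#' Physical storage density of Preview encoding relative to normal encoding
#'
#' With a fraction `f` of unique strands stored as Preview strands at single
#' copy and the remaining full-file strands stored at `c` copies each, the
#' stored physical copies per unique data strand are
#' `D = f + (1 - f) * c` (model `"total"`). The alternative `"fullonly"`
#' model counts only the full-file copies, `D = (1 - f) * c`.
#'
#' @param f preview fraction of unique strands, in (0, 1].
#' @param c stored-copy ratio of full-file strands to preview strands (>= 1).
#' @param model `"total"` (default) or `"fullonly"`.
#' @return density ratio (fold physical space relative to single-copy
#'   encoding). Vectorized over `f` and `c`.
#' @export
density_ratio <- function(f, c, model = c("total", "fullonly")) {
  model <- match.arg(model)
  if (any(f <= 0 | f > 1)) abort("f must lie in (0, 1]")
  if (any(c < 1)) abort("c must be >= 1")
  switch(model,
         total = f + (1 - f) * c,
         fullonly = (1 - f) * c)
}

#' Sequencing cost to find a file with and without Preview
#'
#' Cost unit: fully sequencing one file. Searching a library of `n_files`
#' similar files without Preview means sequencing up to `n_files` full
#' files. With Preview one sequences only each file's Preview strands
#' (a fraction `f` of a file) until the target is found, then the one full
#' file. With `search_all = TRUE` all previews are read
#' (`cost = n_files * f + 1`); otherwise the expected search position
#' `(n_files + 1) / 2` is used for both strategies.
#'
#' @param n_files library size (>= 1).
#' @param f preview fraction, in (0, 1).
#' @param search_all sequence every preview before committing (default TRUE).
#' @param overhead optional per-preview-access read-depth overhead
#'   multiplier (default 1).
#' @return tibble with `cost_preview`, `cost_normal`, `savings`.
#' @export
cost_to_find <- function(n_files, f, search_all = TRUE, overhead = 1) {
  if (any(f <= 0 | f >= 1)) abort("f must lie in (0, 1) for preview search")
  if (any(n_files < 1)) abort("n_files must be >= 1")
  n_eff <- if (search_all) n_files else (n_files + 1) / 2
  cost_preview <- n_eff * f * overhead + 1
  cost_normal <- n_eff
  tibble(n_files = n_files, f = f,
         cost_preview = cost_preview, cost_normal = cost_normal,
         savings = 1 - cost_preview / cost_normal)
}

#' Sweep the Preview economics over parameter grids
#'
#' @param f preview fractions.
#' @param c copy ratios.
#' @param n_files library sizes.
#' @param model density model, see [density_ratio()].
#' @return tibble of class `preview_economics` with one row per
#'   (f, c, n_files) combination: `density_ratio`, `cost_preview`,
#'   `cost_normal`, `savings`.
#' @export
economics_sweep <- function(f = seq(0.01, 0.5, by = 0.01),
                            c = c(5, 10, 100), n_files = 15,
                            model = "total") {
  grid <- tidyr::expand_grid(f = f, c = c, n_files = n_files)
  grid$density_ratio <- density_ratio(grid$f, grid$c, model)
  costs <- cost_to_find(grid$n_files, grid$f)
  grid$cost_preview <- costs$cost_preview
  grid$cost_normal <- costs$cost_normal
  grid$savings <- costs$savings
  class(grid) <- c("preview_economics", class(grid))
  grid
}
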