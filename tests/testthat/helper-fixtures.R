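# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_jpeg_small <- function() {
  if (is.null(.fx$jpeg_small)) {
    .fx$jpeg_small <- make_progressive_jpeg(64, 64, "gradient", 75, seed = 3)
  }
  .fx$jpeg_small
}

fx_library_small <- function() {
  if (is.null(.fx$lib_small)) {
    .fx$lib_small <- encode_file(fx_jpeg_small(), n_partitions = 3, seed = 11)
  }
  .fx$lib_small
}

# the desk-scale study fixture: ~31 kB noise image, 20 RS blocks, partition 1
# holding ~5% of unique strands
fx_jpeg_study <- function() {
  if (is.null(.fx$jpeg_study)) {
    .fx$jpeg_study <- make_progressive_jpeg(224, 224, "noise", 80, seed = 3)
  }
  .fx$jpeg_study
}

fx_library_study <- function() {
  if (is.null(.fx$lib_study)) {
    .fx$lib_study <- encode_file(fx_jpeg_study(), n_partitions = 3, seed = 11)
  }
  .fx$lib_study
}

# results stashed by the end-to-end acceptance run for the conservation check
fx_stash <- function(name, value) assign(name, value, envir = .fx)
fx_get <- function(name) get0(name, envir = .fx)

random_dna_str <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}
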