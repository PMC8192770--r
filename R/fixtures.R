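# Synthetic inputs: progressive JPEG images and noisy sequencing reads.
# Images are rendered deterministically in R and encoded to JPEG through the
# system Python's Pillow (fixtures only; the codec never touches an imaging
# library).

.find_python <- function() {
  for (p in c("python", "python3")) {
    path <- Sys.which(p)
    if (nzchar(path)) return(path)
  }
  abort("no python interpreter on PATH (needed only for JPEG fixture generation)")
}

.render_pixels <- function(width, height, content, seed) {
  withr::with_seed(seed, {
    x <- matrix(rep(seq_len(width), each = height), height, width)
    y <- matrix(rep(seq_len(height), width), height, width)
    rgb <- switch(content,
      gradient = list(r = x / width, g = y / height,
                      b = (x + y) / (width + height)),
      checkerboard = {
        sq <- ((x - 1) %/% 8 + (y - 1) %/% 8) %% 2
        list(r = sq, g = 1 - sq, b = sq * 0.5 + 0.25)
      },
      noise = list(r = matrix(stats::runif(width * height), height),
                   g = matrix(stats::runif(width * height), height),
                   b = matrix(stats::runif(width * height), height)),
      abort("content must be one of gradient, checkerboard, noise"))
    lapply(rgb, function(ch) round(ch * 255))
  })
}

#' Generate a synthetic progressive JPEG
#'
#' Renders a deterministic test image (gradient, checkerboard or seeded
#' noise) and encodes it as a progressive (SOF2) JPEG. A baseline (SOF0)
#' encoding of the same pixels is available as a negative control.
#'
#' @param width,height image dimensions, pixels (<= 512).
#' @param content `"gradient"`, `"checkerboard"` or `"noise"`.
#' @param quality JPEG quality setting (default 75).
#' @param seed integer seed (affects `"noise"` content).
#' @param progressive emit progressive encoding (default TRUE).
#' @return raw vector of JPEG bytes.
#' @export
make_progressive_jpeg <- function(width = 64, height = 64,
                                  content = "gradient", quality = 75,
                                  seed = 3L, progressive = TRUE) {
  stopifnot(width <= 512, height <= 512, width >= 8, height >= 8)
  px <- .render_pixels(width, height, content, seed)
  # interleaved RGB, row-major: binary PPM (P6)
  inter <- integer(3L * width * height)
  inter[seq(1, length(inter), by = 3)] <- as.integer(t(px$r))
  inter[seq(2, length(inter), by = 3)] <- as.integer(t(px$g))
  inter[seq(3, length(inter), by = 3)] <- as.integer(t(px$b))
  ppm <- tempfile(fileext = ".ppm")
  jpg <- tempfile(fileext = ".jpg")
  on.exit(unlink(c(ppm, jpg)), add = TRUE)
  con <- file(ppm, "wb")
  writeBin(charToRaw(sprintf("P6\n%d %d\n255\n", width, height)), con)
  writeBin(as.raw(inter), con)
  close(con)
  script <- paste0(
    "import sys; from PIL import Image; im = Image.open(sys.argv[1]); ",
    "im.save(sys.argv[2], 'JPEG', quality=int(sys.argv[3]), ",
    "progressive=(sys.argv[4] == '1'))")
  status <- system2(.find_python(), c("-c", shQuote(script), shQuote(ppm),
                                      shQuote(jpg), quality,
                                      if (progressive) "1" else "0"))
  if (status != 0 || !file.exists(jpg)) abort("Pillow JPEG encoding failed")
  readBin(jpg, "raw", file.info(jpg)$size)
}

# test-side helper: does a standard decoder parse these JPEG bytes?
jpeg_parses <- function(bytes) {
  f <- tempfile(fileext = ".jpg")
  on.exit(unlink(f), add = TRUE)
  writeBin(bytes, f)
  script <- paste0(
    "import sys; from PIL import Image, ImageFile; ",
    "ImageFile.LOAD_TRUNCATED_IMAGES = True; ",
    "im = Image.open(sys.argv[1]); im.load(); print(im.size[0] * im.size[1])")
  out <- suppressWarnings(
    system2(.find_python(), c("-c", shQuote(script), shQuote(f)),
            stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  is.null(status) && length(out) >= 1 && !is.na(suppressWarnings(as.integer(out[1])))
}

#' Simulate noisy sequencing reads from a strand pool
#'
#' Read counts per strand are Poisson with mean proportional to abundance
#' (overall mean `depth` reads per strand). Each read carries independent
#' per-base errors at rate `per_base_error`; a fraction `indel_fraction` of
#' errors are single-base insertions/deletions, the rest substitutions.
#'
#' @param pool tibble with `id`, `seq` and optionally `abundance` (equal
#'   abundances assumed otherwise); e.g. `simulate_access()$strands` joined
#'   to the library sequences.
#' @param per_base_error total per-base error rate in \[0, 0.2\].
#' @param depth mean reads per strand.
#' @param indel_fraction fraction of errors that are indels (default 0.1).
#' @param seed optional integer seed.
#' @return tibble with `id`, `seq`, `qual` and `source` (origin strand id).
#' @export
make_noisy_reads <- function(pool, per_base_error = 0.01, depth = 30,
                             indel_fraction = 0.1, seed = NULL) {
  stopifnot(per_base_error >= 0, per_base_error <= 0.2)
  ab <- if ("abundance" %in% names(pool)) pool$abundance else rep(1, nrow(pool))
  run <- function() {
    lambda <- depth * nrow(pool) * ab / sum(ab)
    counts <- stats::rpois(nrow(pool), lambda)
    src <- rep.int(seq_len(nrow(pool)), counts)
    seqs <- pool$seq[src]
    n <- length(seqs)
    if (n == 0) {
      return(tibble(id = character(0), seq = character(0),
                    qual = character(0), source = character(0)))
    }
    sub_rate <- per_base_error * (1 - indel_fraction)
    indel_rate <- per_base_error * indel_fraction
    out <- character(n)
    chunk <- 20000L
    for (lo in seq(1, n, by = chunk)) {
      hi <- min(lo + chunk - 1L, n)
      block <- seqs[lo:hi]
      L <- nchar(block[1]) # library strands share one length
      m <- matrix(match(unlist(seq_chars(block)), DNA_BASES),
                  nrow = hi - lo + 1L, byrow = TRUE)
      hit <- which(stats::runif(length(m)) < sub_rate)
      if (length(hit)) {
        m[hit] <- ((m[hit] - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L
      }
      res <- apply(matrix(DNA_BASES[m], nrow = nrow(m)), 1, paste, collapse = "")
      # indels: per-read event counts, applied by string surgery
      nev <- stats::rbinom(length(res), L, indel_rate)
      for (i in which(nev > 0)) {
        s <- res[i]
        for (e in seq_len(nev[i])) {
          p <- sample.int(nchar(s), 1)
          if (stats::runif(1) < 0.5) { # deletion
            s <- paste0(substr(s, 1, p - 1), substr(s, p + 1, nchar(s)))
          } else {                     # insertion
            s <- paste0(substr(s, 1, p), sample(DNA_BASES, 1),
                        substr(s, p + 1, nchar(s)))
          }
        }
        res[i] <- s
      }
      out[lo:hi] <- res
    }
    tibble(id = sprintf("read_%07d", seq_len(n)), seq = out,
           qual = strrep("I", nchar(out)), source = pool$id[src])
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
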