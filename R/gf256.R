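# GF(256) arithmetic and Reed-Solomon coding.
#
# Field: GF(2^8) with primitive polynomial x^8+x^4+x^3+x^2+1 (0x11d),
# generator alpha = 2, first consecutive root alpha^0 (fcr = 0). Symbols are
# integers 0..255. Codeword vectors are ordered highest-degree coefficient
# first, i.e. cw[1] is the first transmitted symbol.

.gf_env <- new.env(parent = emptyenv())

.gf_tables <- function() {
  if (!is.null(.gf_env$exp)) return(invisible())
  exp_t <- integer(512)
  log_t <- integer(256)
  x <- 1L
  for (i in 0:254) {
    exp_t[i + 1] <- x
    log_t[x + 1] <- i
    x <- bitwShiftL(x, 1)
    if (x >= 256L) x <- bitwXor(x, 0x11dL)
  }
  exp_t[256:510] <- exp_t[1:255]
  .gf_env$exp <- exp_t
  .gf_env$log <- log_t
  invisible()
}

gf_mul <- function(a, b) {
  .gf_tables()
  out <- integer(max(length(a), length(b)))
  a <- rep_len(as.integer(a), length(out))
  b <- rep_len(as.integer(b), length(out))
  nz <- a != 0L & b != 0L
  out[nz] <- .gf_env$exp[.gf_env$log[a[nz] + 1L] + .gf_env$log[b[nz] + 1L] + 1L]
  out
}

gf_div <- function(a, b) {
  .gf_tables()
  if (any(b == 0L)) abort("GF(256) division by zero")
  out <- integer(max(length(a), length(b)))
  a <- rep_len(as.integer(a), length(out)); b <- rep_len(as.integer(b), length(out))
  nz <- a != 0L
  out[nz] <- .gf_env$exp[(.gf_env$log[a[nz] + 1L] - .gf_env$log[b[nz] + 1L] + 255L) %% 255L + 1L]
  out
}

gf_pow <- function(i) { .gf_tables(); .gf_env$exp[(as.integer(i) %% 255L) + 1L] }
gf_inv <- function(a) gf_div(1L, a)

gf_poly_scale <- function(p, x) gf_mul(p, x)

gf_poly_add <- function(p, q) {
  n <- max(length(p), length(q))
  bitwXor(c(integer(n - length(p)), p), c(integer(n - length(q)), q))
}

gf_poly_mul <- function(p, q) {
  out <- integer(length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    if (p[i] == 0L) next
    seg <- i:(i + length(q) - 1L)
    out[seg] <- bitwXor(out[seg], gf_mul(p[i], q))
  }
  out
}

gf_poly_eval <- function(p, x) {
  # Horner; x may be a vector of evaluation points
  y <- rep_len(as.integer(p[1]), length(x))
  for (i in seq_along(p)[-1]) y <- bitwXor(gf_mul(y, x), p[i])
  y
}

# generator polynomial for nsym parity symbols (roots alpha^0..alpha^(nsym-1))
rs_generator <- function(nsym) {
  g <- 1L
  for (i in seq_len(nsym) - 1L) g <- gf_poly_mul(g, c(1L, gf_pow(i)))
  g
}

#' Reed-Solomon systematic encoding
#'
#' Appends `nsym` parity symbols to the message (symbols 0..255), producing a
#' codeword of length `length(msg) + nsym` of an RS code with minimum
#' distance `nsym + 1` (MDS).
#'
#' @param msg integer vector of message symbols (0..255).
#' @param nsym number of parity symbols.
#' @return integer codeword vector, message first.
#' @export
rs_encode <- function(msg, nsym) {
  rs_encode_matrix(matrix(as.integer(msg), nrow = 1), nsym)[1, ]
}

# Row-wise systematic RS encoding of a matrix of messages (one message per
# row), vectorized across rows.
rs_encode_matrix <- function(msgs, nsym) {
  g <- rs_generator(nsym)[-1] # monic; drop leading 1
  n <- nrow(msgs); k <- ncol(msgs)
  rem <- matrix(0L, n, nsym)
  for (j in seq_len(k)) {
    factor <- bitwXor(msgs[, j], rem[, 1])
    rem <- cbind(rem[, -1, drop = FALSE], 0L)
    for (s in seq_len(nsym)) {
      rem[, s] <- bitwXor(rem[, s], gf_mul(factor, g[s]))
    }
  }
  cbind(msgs, rem)
}

rs_syndromes <- function(cw, nsym) {
  gf_poly_eval(cw, gf_pow(seq_len(nsym) - 1L))
}

# Berlekamp-Massey over (Forney) syndromes; returns error locator polynomial
# (highest degree first).
.rs_bm <- function(synd, nsym, erase_count = 0L) {
  err_loc <- 1L; old_loc <- 1L
  steps <- nsym - erase_count
  if (steps <= 0) return(err_loc)
  for (i in seq_len(steps) - 1L) {
    K <- i + 1L  # Forney syndromes already fold erasures out
    delta <- synd[K]
    if (length(err_loc) > 1) {
      for (j in seq_len(length(err_loc) - 1L)) {
        delta <- bitwXor(delta, gf_mul(err_loc[length(err_loc) - j], synd[K - j]))
      }
    }
    old_loc <- c(old_loc, 0L)
    if (delta != 0L) {
      if (length(old_loc) > length(err_loc)) {
        new_loc <- gf_poly_scale(old_loc, delta)
        old_loc <- gf_poly_scale(err_loc, gf_inv(delta))
        err_loc <- new_loc
      }
      err_loc <- gf_poly_add(err_loc, gf_poly_scale(old_loc, delta))
    }
  }
  # strip leading zeros
  nz <- which(err_loc != 0L)
  if (!length(nz)) abort("degenerate error locator")
  err_loc[nz[1]:length(err_loc)]
}

#' Reed-Solomon errors-and-erasures decoding
#'
#' Decodes one codeword of a systematic RS code with `nsym` parity symbols,
#' correcting up to floor((nsym - e)/2) symbol errors given `e` declared
#' erasures (2*errors + erasures <= nsym).
#'
#' @param cw integer codeword (message + parity), symbols 0..255. Erased
#'   positions may hold any value (conventionally 0).
#' @param nsym number of parity symbols.
#' @param erasures integer vector of 1-based erased positions (optional).
#' @return list with `ok` (logical), `msg` (corrected message symbols) and
#'   `cw` (corrected codeword); `ok = FALSE` when decoding fails.
#' @export
rs_decode <- function(cw, nsym, erasures = integer(0)) {
  cw <- as.integer(cw)
  n <- length(cw)
  k <- n - nsym
  fail <- list(ok = FALSE, msg = NULL, cw = NULL)
  if (length(erasures) > nsym) return(fail)
  synd <- rs_syndromes(cw, nsym)
  if (all(synd == 0L)) {
    return(list(ok = TRUE, msg = cw[seq_len(k)], cw = cw))
  }
  # coefficient positions (exponents) of erasures
  er_coef <- n - 1L - (erasures - 1L)
  # Forney syndromes: fold erasure information out of the syndromes
  fsynd <- synd
  for (p in er_coef) {
    x <- gf_pow(p)
    if (length(fsynd) > 1) {
      for (j in seq_len(length(fsynd) - 1L)) {
        fsynd[j] <- bitwXor(gf_mul(fsynd[j], x), fsynd[j + 1])
      }
    }
  }
  err_loc <- tryCatch(.rs_bm(fsynd, nsym, length(erasures)),
                      error = function(e) NULL)
  if (is.null(err_loc)) return(fail)
  n_err <- length(err_loc) - 1L
  if (2L * n_err + length(erasures) > nsym) return(fail)
  # Chien search: locator roots lie at alpha^(-p) for error coefficient
  # positions p, so evaluate at alpha^(255-p) for p in 0..n-1
  err_coef <- integer(0)
  if (n_err > 0) {
    pcand <- seq_len(n) - 1L
    ev <- gf_poly_eval(err_loc, gf_pow((255L - pcand) %% 255L))
    err_coef <- pcand[ev == 0L]
    if (length(err_coef) != n_err) return(fail)
  }
  all_coef <- c(er_coef, err_coef)
  if (!length(all_coef)) return(fail)
  # errata locator over all positions
  loc <- 1L
  for (p in all_coef) loc <- gf_poly_mul(loc, c(gf_pow(p), 1L))
  # error evaluator: omega(x) = [S(x) * Lambda(x)] mod x^nsym
  synd_rev <- rev(synd)
  om_full <- gf_poly_mul(synd_rev, loc)
  keep <- min(length(om_full), nsym)
  omega <- om_full[(length(om_full) - keep + 1L):length(om_full)]
  # Forney algorithm, batched over all errata positions. With fcr = 0,
  # Lambda'(Xi^-1) = Xi * prod_{j != i}(1 + Xi^-1 Xj) and the Xi factors
  # cancel against the numerator.
  X <- gf_pow(all_coef)
  Xi_inv <- gf_inv(X)
  ne <- length(all_coef)
  terms <- matrix(bitwXor(1L, gf_mul(rep(Xi_inv, times = ne),
                                     rep(X, each = ne))),
                  nrow = ne) # terms[i, j] = 1 + Xi_inv[i] * X[j]
  diag(terms) <- 1L
  if (any(terms == 0L)) return(fail)
  primes <- gf_pow(rowSums(matrix(.gf_env$log[terms + 1L], nrow = ne)))
  y <- gf_poly_eval(omega, Xi_inv)
  mags <- gf_div(y, primes)
  pos <- n - all_coef
  if (any(pos < 1L | pos > n)) return(fail)
  corrected <- cw
  corrected[pos] <- bitwXor(corrected[pos], mags)
  if (any(rs_syndromes(corrected, nsym) != 0L)) return(fail)
  list(ok = TRUE, msg = corrected[seq_len(k)], cw = corrected)
}

# Syndrome screen across many rows at once: returns logical vector, TRUE if
# the row is already a valid codeword (all syndromes zero).
rs_clean_rows <- function(cwm, nsym) {
  xs <- gf_pow(seq_len(nsym) - 1L)
  ok <- rep(TRUE, nrow(cwm))
  for (s in seq_len(nsym)) {
    y <- rep_len(cwm[, 1], nrow(cwm))
    for (j in seq_len(ncol(cwm))[-1]) y <- bitwXor(gf_mul(y, xs[s]), cwm[, j])
    ok <- ok & (y == 0L)
  }
  ok
}
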