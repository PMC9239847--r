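#' @keywords internal
"_PACKAGE"

## Deterministic seed derivation: one global seed expands to child seeds via a
## counter scheme so partial regeneration (e.g. one participant) is reproducible.
## Constants are from the MINSTD generator family; result always < 2^31 - 1.
child_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483629
  s <- as.double(seed %% m)
  for (k in seq_along(idx)) {
    s <- (s * 48271 + as.double(idx[k]) * 16807 + k * 69621) %% m
  }
  as.integer(s)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## softplus rectifier used to make generated envelopes/apertures nonnegative;
## near-identity for x >> 0 so the rank-based copula downstream is unaffected.
softplus <- function(x) {
  out <- x
  low <- x < 30
  out[low] <- log1p(exp(x[low]))
  out
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## circular shift: result[t] = x[t - s] (s may be negative); for matrices the
## shift applies jointly to all columns (rows move together).
circ_shift <- function(x, s) {
  if (is.matrix(x)) n <- nrow(x) else n <- length(x)
  if (n == 0L) return(x)
  s <- as.integer(s %% n)
  if (s == 0L) return(x)
  idx <- c((n - s + 1L):n, seq_len(n - s))
  if (is.matrix(x)) x[idx, , drop = FALSE] else x[idx]
}

## R's mixed-radix FFT degrades to O(n * p) for a large prime factor p;
## records of arbitrary length (concatenated trials) can hit such sizes, so
## fall back to the Bluestein chirp-z algorithm (three smooth-length FFTs).
.is_fft_smooth <- function(n) {
  if (n < 1024L) return(TRUE)
  for (p in c(2L, 3L, 5L, 7L, 11L, 13L)) while (n %% p == 0L) n <- n %/% p
  n == 1L
}

.bluestein <- function(x, inverse = FALSE) {
  n <- length(x)
  if (inverse) return(Conj(.bluestein(Conj(x))))
  j <- seq_len(n) - 1
  c_chirp <- exp(complex(imaginary = -pi * (j * j %% (2 * n)) / n))
  m <- stats::nextn(2L * n - 1L, 2)
  A <- stats::fft(c(x * c_chirp, rep(0, m - n)))
  bfull <- Conj(c_chirp)
  B <- stats::fft(c(bfull, rep(0, m - 2L * n + 1L), bfull[n:2]))
  conv <- stats::fft(A * B, inverse = TRUE)[seq_len(n)] / m
  c_chirp * conv
}

## fft/mvfft with the same semantics as stats::fft (inverse unnormalized)
fft_any <- function(x, inverse = FALSE) {
  if (is.matrix(x)) {
    if (.is_fft_smooth(nrow(x))) return(stats::mvfft(x, inverse = inverse))
    out <- vapply(seq_len(ncol(x)), function(j) .bluestein(x[, j], inverse),
                  complex(nrow(x)))
    return(matrix(out, nrow(x), ncol(x)))
  }
  if (.is_fft_smooth(length(x))) stats::fft(x, inverse = inverse)
  else .bluestein(x, inverse)
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  invisible(x)
}
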