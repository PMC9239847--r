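## Gaussian-copula mutual information core.
##
## Dependence between blocks of (possibly complex-valued) signals is estimated
## by rank-normalizing every real dimension to a standard-normal marginal (the
## Gaussian copula), then computing Gaussian entropies of the transformed
## blocks with an analytic small-sample bias correction.  Because only ranks
## enter, the estimator is invariant to any dimension-wise strictly monotone
## transform of the inputs, and MI/CMI come out in bits.

#' Split a complex block into paired real/imaginary columns
#'
#' Complex analytic signals carry phase and amplitude jointly; each complex
#' column becomes two real columns (real, imaginary) so that both enter the
#' copula estimator.  Real input is returned as a plain matrix unchanged.
#'
#' @param x numeric or complex vector/matrix (samples in rows).
#' @return real-valued matrix with one or two columns per input column.
#' @export
as_real_block <- function(x) {
  if (is.null(x)) return(NULL)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  if (is.complex(x)) {
    out <- matrix(0, nrow(x), 2L * ncol(x))
    for (j in seq_len(ncol(x))) {
      out[, 2L * j - 1L] <- Re(x[, j])
      out[, 2L * j] <- Im(x[, j])
    }
    out
  } else {
    storage.mode(x) <- "double"
    x
  }
}

#' Gaussian-copula rank normalization
#'
#' Maps each column through the empirical rank transform followed by the
#' standard-normal quantile function at rank/(n+1).  Ties are broken by order
#' of appearance (stable), so output is deterministic.
#'
#' @param x numeric or complex vector/matrix; complex columns are split into
#'   real/imaginary pairs first.
#' @return matrix of the same number of rows with standard-normal marginals.
#' @export
copula_normalize <- function(x) {
  x <- as_real_block(x)
  n <- nrow(x)
  if (n < 3L) stop("copula_normalize: need at least 3 samples", call. = FALSE)
  out <- matrix(0, n, ncol(x))
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    if (!all(is.finite(v))) stop("copula_normalize: non-finite values in dimension ", j, call. = FALSE)
    if (diff(range(v)) == 0)
      stop("copula_normalize: dimension ", j, " is constant (rank degenerate)", call. = FALSE)
    out[, j] <- stats::qnorm(rank(v, ties.method = "first") / (n + 1))
  }
  out
}

#' Bias-corrected Gaussian entropy in bits
#'
#' Differential entropy 0.5*log2((2*pi*e)^d det(C)) of a d-dimensional
#' Gaussian with covariance `C`, minus the analytic small-sample bias of the
#' log-determinant of a covariance estimated from `n` samples: for a Wishart
#' sample covariance, E[log det S] exceeds log det Sigma by
#' sum_i psi((n-i)/2) + d log(2/(n-1)), which is subtracted here.
#'
#' @param cov covariance matrix (positive definite).
#' @param n number of samples the covariance was estimated from.
#' @return entropy in bits.
#' @export
gaussian_entropy_bits <- function(cov, n) {
  cov <- as.matrix(cov)
  d <- ncol(cov)
  ch <- tryCatch(chol(cov), error = function(e) NULL)
  if (is.null(ch) || kappa(cov, exact = FALSE) > 1e12) {
    bad <- which(abs(stats::cov2cor(cov) - 1) < 1e-10 &
                   upper.tri(cov), arr.ind = TRUE)
    stop("gaussian_entropy_bits: singular/ill-conditioned covariance",
         if (nrow(bad)) paste0(" (collinear dimensions: ",
                               paste(apply(bad, 1, paste, collapse = "~"), collapse = ", "), ")"),
         call. = FALSE)
  }
  h_nats <- sum(log(diag(ch))) + 0.5 * d * log(2 * pi * exp(1))
  bias_nats <- 0.5 * (sum(digamma((n - seq_len(d)) / 2)) + d * log(2 / (n - 1)))
  (h_nats - bias_nats) / log(2)
}

## lean entropy from covariance (no conditioning diagnostics; hot path)
.h_chol <- function(C, n) {
  d <- ncol(C)
  h_nats <- sum(log(diag(chol(C)))) + 0.5 * d * log(2 * pi * exp(1))
  bias_nats <- 0.5 * (sum(digamma((n - seq_len(d)) / 2)) + d * log(2 / (n - 1)))
  (h_nats - bias_nats) / log(2)
}

## entropy of a subset of dimensions of a joint covariance
.h_sub <- function(C, n, ix) .h_chol(C[ix, ix, drop = FALSE], n)

## conditioning check used once per public estimator call
.check_joint_cov <- function(C) {
  if (kappa(C, exact = FALSE) > 1e12) {
    cr <- stats::cov2cor(C)
    bad <- which(abs(cr) > 1 - 1e-10 & upper.tri(cr), arr.ind = TRUE)
    stop("singular/ill-conditioned joint covariance",
         if (nrow(bad)) paste0(" (collinear dimensions: ",
                               paste(apply(bad, 1, paste, collapse = "~"), collapse = ", "), ")"),
         call. = FALSE)
  }
  invisible(C)
}

## covariance with 1/(n-1) normalization of copula-normalized columns
.cov_blocks <- function(...) {
  m <- cbind(...)
  n <- nrow(m)
  m <- sweep(m, 2L, colMeans(m))
  crossprod(m) / (n - 1)
}

.check_n <- function(n, d) {
  if (n <= 10 * d)
    warning(sprintf("sample count n=%d is small for total dimensionality d=%d (want n > 10d)", n, d),
            call. = FALSE)
}

.mi_estimate <- function(value, kind, baseline_subtracted = FALSE, metadata = list()) {
  structure(list(value = value, kind = kind,
                 baseline_subtracted = baseline_subtracted,
                 metadata = metadata),
            class = "mi_estimate")
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(sprintf("<mi_estimate> %s%s: %.5f bits\n", x$kind,
              if (isTRUE(x$baseline_subtracted)) " (baseline-subtracted)" else "",
              x$value))
  if (length(x$metadata)) {
    md <- x$metadata[!vapply(x$metadata, is.null, logical(1))]
    if (length(md)) cat("  ", paste(names(md), unlist(lapply(md, format)), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Gaussian-copula mutual information
#'
#' Computes I(X;Y) = H(X) + H(Y) - H(X,Y) in bits on copula-normalized blocks
#' with bias-corrected Gaussian entropies.  Complex inputs are expanded into
#' real/imaginary column pairs, so a single analytic signal contributes two
#' dimensions (phase and amplitude information jointly).
#'
#' @param x,y vectors or matrices (numeric or complex), samples in rows.
#' @param metadata optional named list attached to the estimate.
#' @return an `mi_estimate` (kind "mi"); `value` is in bits.
#' @export
gcmi <- function(x, y, metadata = list()) {
  cx <- copula_normalize(x)
  cy <- copula_normalize(y)
  if (nrow(cx) != nrow(cy)) stop("gcmi: x and y must have the same number of samples", call. = FALSE)
  n <- nrow(cx)
  p <- ncol(cx); q <- ncol(cy)
  .check_n(n, p + q)
  C <- .cov_blocks(cx, cy)
  .check_joint_cov(C)
  v <- .h_sub(C, n, 1:p) + .h_sub(C, n, p + 1:q) - .h_chol(C, n)
  .mi_estimate(v, "mi", metadata = metadata)
}

#' Gaussian-copula conditional mutual information
#'
#' Implements the four-entropy identity
#' I(X;Y|Z) = H(X,Z) + H(Y,Z) - H(X,Y,Z) - H(Z)
#' on copula-normalized blocks, in bits.  Used both for partialling one
#' feature group out of another's tracking and (with a time-shifted copy of X
#' as Z) for bias-matched MI estimation.
#'
#' @param x,y,z vectors or matrices (numeric or complex), samples in rows;
#'   `z` is the conditioning block.
#' @param metadata optional named list attached to the estimate.
#' @return an `mi_estimate` (kind "cmi"); `value` is in bits.
#' @export
gcmi_conditional <- function(x, y, z, metadata = list()) {
  if (is.null(z)) stop("gcmi_conditional: conditioning block z is required", call. = FALSE)
  cx <- copula_normalize(x)
  cy <- copula_normalize(y)
  cz <- copula_normalize(z)
  n <- nrow(cx)
  if (nrow(cy) != n || nrow(cz) != n)
    stop("gcmi_conditional: all blocks must share the sample count", call. = FALSE)
  p <- ncol(cx); q <- ncol(cy); r <- ncol(cz)
  .check_n(n, p + q + r)
  C <- .cov_blocks(cx, cy, cz)
  .check_joint_cov(C)
  ix <- 1:p; iy <- p + 1:q; iz <- p + q + 1:r
  v <- .h_sub(C, n, c(ix, iz)) + .h_sub(C, n, c(iy, iz)) -
    .h_chol(C, n) - .h_sub(C, n, iz)
  .mi_estimate(v, "cmi", metadata = metadata)
}

## Fast paths used by the tracking layer: MI/CMI straight from an assembled
## joint covariance of already-normalized blocks (no re-ranking).
.mi_from_cov <- function(C, n, ix, iy) {
  .h_sub(C, n, ix) + .h_sub(C, n, iy) - .h_sub(C, n, c(ix, iy))
}

.cmi_from_cov <- function(C, n, ix, iy, iz) {
  .h_sub(C, n, c(ix, iz)) + .h_sub(C, n, c(iy, iz)) -
    .h_sub(C, n, c(ix, iy, iz)) - .h_sub(C, n, iz)
}
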