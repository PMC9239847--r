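## Band preparation: trial concatenation, zero-phase band-pass filtering and
## the complex analytic-signal representation used by the MI layer.
##
## Order of operations follows the analysis convention: concatenate trials
## (discarding the onset-transient window), filter the concatenated record,
## then take the Hilbert transform of the whole record.

#' Frequency band specification
#'
#' @param low,high band edges in Hz; must satisfy 0 < low < high <= 25
#'   (Nyquist of the 50 Hz working rate).
#' @param label optional label; defaults to "low-high".
#' @param filter_order Butterworth order for the one-pass filter (default 3).
#' @return an object of class `band_spec`.
#' @export
band_spec <- function(low, high, label = NULL, filter_order = 3L) {
  stopifnot_scalar(low, "low"); stopifnot_scalar(high, "high")
  if (!(low > 0 && low < high && high <= 25))
    stop("band_spec: need 0 < low < high <= 25 Hz", call. = FALSE)
  structure(list(low = low, high = high,
                 label = if (is.null(label)) sprintf("%g-%g", low, high) else label,
                 filter_order = as.integer(filter_order)),
            class = "band_spec")
}

#' Canonical analysis bands
#'
#' The delta/theta bands typically used to study dynamic speech encoding:
#' 0.5-1, 1-3, 2-4, 3-6, 4-8 and the broad 0.5-8 Hz band.
#'
#' @return named list of `band_spec` objects.
#' @export
canonical_bands <- function() {
  specs <- list(c(0.5, 1), c(1, 3), c(2, 4), c(3, 6), c(4, 8), c(0.5, 8))
  out <- lapply(specs, function(b) band_spec(b[1], b[2]))
  names(out) <- vapply(out, `[[`, "", "label")
  out
}

## zero-phase forward-backward IIR with odd-reflection padding (~3x the
## slowest time constant of the band) to suppress edge transients on short
## records; signal::filter does the per-pass work.
.zero_phase <- function(b, a, x, padlen) {
  n <- length(x)
  padlen <- min(padlen, n - 1L)
  xp <- c(2 * x[1] - x[(padlen + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - padlen)])
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(padlen + 1L):(padlen + n)]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward third-order Butterworth band-pass: zero net phase shift,
#' effective magnitude response equal to the squared one-pass response.
#'
#' @param x numeric vector or matrix (time in rows; columns filtered
#'   independently).
#' @param band a [band_spec()].
#' @param rate sampling rate in Hz (default 50).
#' @return filtered series, same shape as `x`.
#' @export
bandpass_zero_phase <- function(x, band, rate = 50) {
  stopifnot(inherits(band, "band_spec"))
  nyq <- rate / 2
  if (band$high >= nyq) stop("bandpass_zero_phase: band edge at or above Nyquist", call. = FALSE)
  bf <- signal::butter(band$filter_order, c(band$low, band$high) / nyq, type = "pass")
  padlen <- ceiling(3 * rate / band$low)
  n <- if (is.matrix(x)) nrow(x) else length(x)
  if (n <= 3L * band$filter_order * 2L)
    stop("bandpass_zero_phase: record shorter than 3x the filter settling length", call. = FALSE)
  f1 <- function(v) .zero_phase(bf$b, bf$a, v, padlen)
  if (is.matrix(x)) apply(x, 2L, f1) else f1(x)
}

#' Concatenate trials along time, discarding the onset window
#'
#' Drops the first `discard_initial` seconds of every trial (onset-transient
#' removal) and concatenates the remainders along the time dimension,
#' recording trial boundaries for shift bookkeeping.
#'
#' @param trials list of numeric vectors or matrices (time in rows) sharing a
#'   channel set.
#' @param rate sampling rate in Hz (default 50).
#' @param discard_initial seconds discarded at each trial start (default 0.5).
#' @return list with `data` (matrix, time x channels), `boundaries`
#'   (data.frame of trial, start, length) and `rate`.
#' @export
concatenate_trials <- function(trials, rate = 50, discard_initial = 0.5) {
  stopifnot(is.list(trials), length(trials) > 0)
  drop_n <- round(discard_initial * rate)
  pieces <- vector("list", length(trials))
  for (k in seq_along(trials)) {
    tr <- trials[[k]]
    if (!is.matrix(tr)) tr <- matrix(tr, ncol = 1L)
    if (nrow(tr) <= drop_n)
      stop(sprintf("concatenate_trials: trial %d (%d samples) shorter than the %g s discard window",
                   k, nrow(tr), discard_initial), call. = FALSE)
    pieces[[k]] <- tr[(drop_n + 1L):nrow(tr), , drop = FALSE]
  }
  lens <- vapply(pieces, nrow, 0L)
  starts <- cumsum(c(1L, lens[-length(lens)]))
  list(data = do.call(rbind, pieces),
       boundaries = data.frame(trial = seq_along(trials), start = starts, length = lens),
       rate = rate)
}

#' Analytic signal via the Hilbert transform
#'
#' Computes the complex analytic signal per column over the whole record
#' (FFT method): the real part equals the input, the imaginary part is its
#' Hilbert transform.
#'
#' @param x band-limited numeric vector or matrix (time in rows).
#' @param band optional `band_spec` recorded as an attribute.
#' @return complex vector/matrix of class `analytic_band_signal`.
#' @export
analytic_signal <- function(x, band = NULL) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fx <- fft_any(x)
  out <- fft_any(fx * h, inverse = TRUE) / n
  if (vec) out <- out[, 1]
  structure(out, band = band, class = c("analytic_band_signal", class(out)))
}

#' Concatenate, band-filter and Hilbert-transform a set of trials
#'
#' Convenience wrapper applying the canonical order: concatenate (discard
#' onsets) -> zero-phase band-pass -> analytic signal.
#'
#' @inheritParams concatenate_trials
#' @param band a [band_spec()].
#' @return list with complex `analytic` (time x channels), `boundaries`,
#'   `band`, `rate`.
#' @export
prep_band <- function(trials, band, rate = 50, discard_initial = 0.5) {
  cc <- concatenate_trials(trials, rate = rate, discard_initial = discard_initial)
  filt <- bandpass_zero_phase(cc$data, band, rate = rate)
  if (!is.matrix(filt)) filt <- matrix(filt, ncol = 1L)
  list(analytic = unclass(analytic_signal(filt, band = band)),
       boundaries = cc$boundaries, band = band, rate = rate)
}
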