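## Stimulus feature extraction: broadband amplitude envelope (mean of 12
## band-limited Hilbert envelopes), its slope, a frame-wise autocorrelation
## pitch (F0) estimate, lip-aperture features, and Welch power spectra /
## magnitude-squared coherence between features.

#' Names of the six stimulus features
#' @export
feature_names <- function() c("aud_env", "aud_slope", "aud_pitch",
                              "lip_area", "lip_slope", "lip_width")

#' Feature groups of equal dimensionality
#'
#' The three acoustic features (AudFeat) and the three lip features
#' (LipFeat); both groups have three members so group-level MI values are
#' comparable.
#' @return named list of character vectors.
#' @export
feature_groups <- function() {
  list(AudFeat = c("aud_env", "aud_slope", "aud_pitch"),
       LipFeat = c("lip_area", "lip_slope", "lip_width"))
}

## Band boundaries for the envelope filterbank, in Hz: 12 logarithmically
## spaced bands between 0.1 and 10 kHz.
.env_band_edges <- function() {
  c(0.1, 0.18, 0.3, 0.46, 0.68, 0.98, 1.39, 2.0, 2.73, 3.79, 5.25, 7.25, 10) * 1000
}

#' Broadband amplitude envelope of an acoustic waveform
#'
#' Filters the waveform into 12 logarithmically spaced bands between 0.1 and
#' 10 kHz (zero-phase third-order Butterworth), takes the magnitude of the
#' analytic signal in each band, averages the 12 band envelopes, low-pass
#' filters (anti-alias, 20 Hz cutoff) and resamples to 50 Hz.
#'
#' @param waveform numeric vector, mono audio.
#' @param fs audio sampling rate in Hz; must be at least 20 kHz so the top
#'   band is representable.
#' @param out_rate output rate in Hz (default 50).
#' @return numeric vector (nonnegative) at `out_rate`, with attribute
#'   `rate`.
#' @export
compute_broadband_envelope <- function(waveform, fs, out_rate = 50) {
  if (fs < 2 * 10000) stop("compute_broadband_envelope: fs must be >= 20 kHz (top band 7.25-10 kHz)", call. = FALSE)
  if (!all(is.finite(waveform))) stop("compute_broadband_envelope: non-finite samples", call. = FALSE)
  edges <- .env_band_edges()
  nyq <- fs / 2
  env_sum <- numeric(length(waveform))
  for (b in seq_len(length(edges) - 1L)) {
    bf <- signal::butter(3, c(edges[b], edges[b + 1]) / nyq, type = "pass")
    padlen <- min(length(waveform) - 1L, ceiling(3 * fs / edges[b]))
    xb <- .zero_phase(bf$b, bf$a, waveform, padlen)
    env_sum <- env_sum + Mod(analytic_signal(xb))
  }
  env <- env_sum / (length(edges) - 1L)
  .resample_to(env, fs, out_rate)
}

## anti-aliased resampling: zero-phase low-pass at 0.8 x target Nyquist, then
## linear interpolation onto the target grid
.resample_to <- function(x, fs, out_rate) {
  cutoff <- 0.8 * out_rate / 2
  bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
  padlen <- min(length(x) - 1L, ceiling(3 * fs / cutoff))
  xf <- .zero_phase(bf$b, bf$a, x, padlen)
  n_out <- round(length(x) / fs * out_rate)
  t_out <- (seq_len(n_out) - 1L) / out_rate
  out <- stats::approx(x = (seq_along(x) - 1L) / fs, y = xf, xout = t_out, rule = 2)$y
  out <- pmax(out, 0)
  attr(out, "rate") <- out_rate
  out
}

#' Slope (first derivative) of a feature time series
#'
#' First difference with the leading value set to 0 by convention, so output
#' length equals input length and all features stay time-aligned.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @export
compute_slope <- function(x) {
  r <- attr(x, "rate")
  out <- c(0, diff(as.numeric(x)))
  attr(out, "rate") <- r
  out
}

#' Frame-wise fundamental-frequency (pitch) estimate
#'
#' Short-time autocorrelation F0 tracker: 40-ms frames stepped to match the
#' 50 Hz output grid, F0 search range 60-300 Hz, parabolic peak
#' interpolation.  Frames are flagged unvoiced when the normalized
#' autocorrelation peak falls below `voicing_threshold` or frame energy is
#' negligible; unvoiced frames are linearly interpolated across gaps (the MI
#' analysis needs a complete series) and flagged in the output.
#'
#' @param waveform mono audio vector.
#' @param fs audio sampling rate (Hz).
#' @param fmin,fmax F0 search range in Hz.
#' @param frame_sec analysis frame length in seconds.
#' @param out_rate output rate (default 50 Hz).
#' @param voicing_threshold normalized autocorrelation threshold (default 0.3).
#' @return list with `samples` (F0 in Hz at `out_rate`, interpolated),
#'   `voiced` (logical per frame), `rate`.
#' @export
estimate_pitch <- function(waveform, fs, fmin = 60, fmax = 300,
                           frame_sec = 0.04, out_rate = 50,
                           voicing_threshold = 0.3) {
  n <- length(waveform)
  half <- round(frame_sec * fs / 2)
  n_frames <- max(1L, floor(n / fs * out_rate))
  lag_min <- max(2L, floor(fs / fmax))
  lag_max <- ceiling(fs / fmin)
  f0 <- rep(NA_real_, n_frames)
  rms <- numeric(n_frames)
  for (k in seq_len(n_frames)) {
    c0 <- round((k - 1) * fs / out_rate) + 1L
    i0 <- max(1L, c0 - half); i1 <- min(n, c0 + half)
    fr <- waveform[i0:i1]
    fr <- fr - mean(fr)
    rms[k] <- sqrt(mean(fr^2))
    if (rms[k] < 1e-6 || length(fr) <= lag_max) next
    ac <- stats::acf(fr, lag.max = lag_max, plot = FALSE, demean = FALSE)$acf[, 1, 1]
    seg <- ac[(lag_min + 1L):(lag_max + 1L)]
    pk <- which.max(seg)
    if (seg[pk] < voicing_threshold) next
    lag <- lag_min + pk - 1L
    # parabolic interpolation around the integer-lag peak
    if (pk > 1L && pk < length(seg)) {
      y0 <- seg[pk - 1L]; y1 <- seg[pk]; y2 <- seg[pk + 1L]
      den <- y0 - 2 * y1 + y2
      if (abs(den) > 1e-12) lag <- lag + 0.5 * (y0 - y2) / den
    }
    f0[k] <- fs / lag
  }
  voiced <- !is.na(f0)
  if (!any(voiced)) {
    warning("estimate_pitch: no voiced frames detected; interpolation skipped")
    return(list(samples = f0, voiced = voiced, rate = out_rate))
  }
  samples <- f0
  if (any(!voiced)) {
    samples <- stats::approx(x = which(voiced), y = f0[voiced],
                             xout = seq_len(n_frames), rule = 2)$y
  }
  list(samples = samples, voiced = voiced, rate = out_rate)
}

#' Lip aperture features from a 25-fps lip trace
#'
#' Takes a table of lip area and width sampled at a nominal 25 fps, computes
#' the slope of the lip area at the native rate, then linearly interpolates
#' all three series to 50 Hz on the closed time interval.
#'
#' @param lip_table data.frame with columns `time` (seconds, strictly
#'   increasing), `lip_area`, `lip_width`.
#' @param out_rate output rate (default 50 Hz).
#' @param max_gap largest tolerated inter-frame gap in seconds (default 0.2).
#' @return named list of numeric vectors `lip_area`, `lip_slope`,
#'   `lip_width` at `out_rate` (attribute `rate`).
#' @export
extract_lip_features <- function(lip_table, out_rate = 50, max_gap = 0.2) {
  stopifnot(all(c("time", "lip_area", "lip_width") %in% names(lip_table)))
  tt <- lip_table$time
  if (any(diff(tt) <= 0)) stop("extract_lip_features: time stamps must be strictly increasing", call. = FALSE)
  if (any(diff(tt) > max_gap))
    stop(sprintf("extract_lip_features: gap of %.3f s exceeds %.3f s", max(diff(tt)), max_gap), call. = FALSE)
  slope25 <- c(0, diff(lip_table$lip_area))
  t_out <- seq(tt[1], tt[length(tt)], by = 1 / out_rate)
  interp <- function(v) stats::approx(tt, v, xout = t_out, rule = 2)$y
  out <- list(lip_area = interp(lip_table$lip_area),
              lip_slope = interp(slope25),
              lip_width = interp(lip_table$lip_width))
  for (k in seq_along(out)) attr(out[[k]], "rate") <- out_rate
  out
}

## Welch segment bookkeeping: Hann-windowed, mean-removed segments with 50%
## overlap; returns accumulated one-sided auto-/cross-spectra.
.welch_segments <- function(x, y, rate, win_sec, overlap) {
  nw <- round(win_sec * rate)
  step <- max(1L, round(nw * (1 - overlap)))
  n <- length(x)
  if (n < nw) return(NULL)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1))
  starts <- seq(1L, n - nw + 1L, by = step)
  nf <- floor(nw / 2) + 1L
  sxx <- syy <- numeric(nf)
  sxy <- complex(nf)
  for (s0 in starts) {
    xi <- x[s0:(s0 + nw - 1L)]; xi <- (xi - mean(xi)) * w
    fx <- stats::fft(xi)[1:nf]
    sxx <- sxx + Mod(fx)^2
    if (!is.null(y)) {
      yi <- y[s0:(s0 + nw - 1L)]; yi <- (yi - mean(yi)) * w
      fy <- stats::fft(yi)[1:nf]
      syy <- syy + Mod(fy)^2
      sxy <- sxy + fx * Conj(fy)
    }
  }
  scale <- 1 / (rate * sum(w^2))
  list(freq = (seq_len(nf) - 1L) * rate / nw,
       sxx = sxx * scale, syy = syy * scale, sxy = sxy * scale,
       n_segments = length(starts))
}

#' Welch power spectrum (and cross-spectrum) of one record
#'
#' Hann-windowed Welch estimate with 1-s segments and 50% overlap by
#' default.
#'
#' @param x numeric vector.
#' @param y optional second vector (same length) for cross-spectral output.
#' @param rate sampling rate in Hz.
#' @param win_sec segment length in seconds (default 1).
#' @param overlap fractional segment overlap (default 0.5).
#' @return list with `freq`, `sxx` and, when `y` is given, `syy`, `sxy`,
#'   `coherence` (magnitude-squared); plus `n_segments`.
#' @export
welch_spectra <- function(x, y = NULL, rate = 50, win_sec = 1, overlap = 0.5) {
  if (!is.null(y) && length(y) != length(x)) stop("welch_spectra: x and y lengths differ", call. = FALSE)
  seg <- .welch_segments(as.numeric(x), if (is.null(y)) NULL else as.numeric(y),
                         rate, win_sec, overlap)
  if (is.null(seg)) stop("welch_spectra: record shorter than one window", call. = FALSE)
  if (!is.null(y)) seg$coherence <- Mod(seg$sxy)^2 / pmax(seg$sxx * seg$syy, .Machine$double.xmin)
  seg
}

#' Spectra and band-averaged coherence across a cohort of trials
#'
#' For each feature: Welch power spectra per trial, log-transformed and
#' averaged across trials.  For each requested feature pair:
#' magnitude-squared coherence from cross-spectra pooled over every segment
#' of every trial, plus averages over the requested frequency bands.
#'
#' @param trials list of matrices (time x features, named columns) at a
#'   common rate.
#' @param pairs list of length-2 character vectors naming feature pairs
#'   (default envelope vs lip area).
#' @param rate sampling rate (default 50 Hz).
#' @param bands list of c(low, high) ranges in Hz for band averaging
#'   (default 0.5-1 and 1-3 Hz).
#' @param win_sec,overlap Welch parameters (1-s windows, 50% overlap).
#' @return list with `freq`, `log_psd` (feature x frequency, mean log10
#'   power), `coherence` (named list per pair), `band_coherence`
#'   (data.frame pair x band), `n_segments`.
#' @export
feature_spectra_and_coherence <- function(trials,
                                          pairs = list(c("aud_env", "lip_area")),
                                          rate = 50,
                                          bands = list(c(0.5, 1), c(1, 3)),
                                          win_sec = 1, overlap = 0.5) {
  stopifnot(is.list(trials), length(trials) > 0)
  feats <- colnames(trials[[1]])
  nw <- round(win_sec * rate)
  nf <- floor(nw / 2) + 1L
  freq <- (seq_len(nf) - 1L) * rate / nw
  log_acc <- matrix(0, length(feats), nf, dimnames = list(feats, NULL))
  log_cnt <- 0L
  pair_acc <- lapply(pairs, function(p) list(sxx = numeric(nf), syy = numeric(nf),
                                             sxy = complex(nf), n = 0L))
  skipped <- 0L
  for (tr in trials) {
    if (nrow(tr) < nw) { skipped <- skipped + 1L; next }
    psd <- sapply(feats, function(f)
      .welch_segments(tr[, f], NULL, rate, win_sec, overlap)$sxx)
    log_acc <- log_acc + t(log10(pmax(psd, .Machine$double.xmin)))
    log_cnt <- log_cnt + 1L
    for (k in seq_along(pairs)) {
      seg <- .welch_segments(tr[, pairs[[k]][1]], tr[, pairs[[k]][2]],
                             rate, win_sec, overlap)
      pair_acc[[k]]$sxx <- pair_acc[[k]]$sxx + seg$sxx * seg$n_segments
      pair_acc[[k]]$syy <- pair_acc[[k]]$syy + seg$syy * seg$n_segments
      pair_acc[[k]]$sxy <- pair_acc[[k]]$sxy + seg$sxy * seg$n_segments
      pair_acc[[k]]$n <- pair_acc[[k]]$n + seg$n_segments
    }
  }
  if (skipped > 0L)
    warning(sprintf("feature_spectra_and_coherence: skipped %d trial(s) shorter than one window", skipped))
  if (log_cnt == 0L) stop("feature_spectra_and_coherence: no trial long enough for one window", call. = FALSE)
  coh <- lapply(pair_acc, function(a)
    Mod(a$sxy)^2 / pmax(a$sxx * a$syy, .Machine$double.xmin))
  names(coh) <- vapply(pairs, paste, "", collapse = ":")
  bc <- do.call(rbind, lapply(seq_along(pairs), function(k) {
    data.frame(pair = names(coh)[k],
               band = vapply(bands, function(b) sprintf("%g-%g", b[1], b[2]), ""),
               coherence = vapply(bands, function(b)
                 mean(coh[[k]][freq >= b[1] & freq <= b[2]]), 0))
  }))
  list(freq = freq, log_psd = log_acc / log_cnt, coherence = coh,
       band_coherence = bc,
       n_segments = vapply(pair_acc, function(a) a$n, 0L))
}
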