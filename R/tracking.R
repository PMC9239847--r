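## Estimation layer: bias-matched MI, surrogate null baselines, lag search
## and windowed MI per participant x condition x ROI x band x feature set.
##
## Lags and surrogate shifts are both realized as circular shifts of the
## concatenated record.  Because the copula transform commutes with a
## circular shift (ranks of a shifted series are the shifted ranks) and a
## joint circular shift leaves within-block covariances untouched, every
## shifted-block covariance needed by an estimator reduces to a circular
## cross-covariance of the normalized columns, which keeps surrogate
## ensembles cheap.

## sample covariance of copula-normalized blocks (columns have exact zero mean)
.ncov <- function(a, b = NULL) {
  n <- nrow(a)
  if (is.null(b)) crossprod(a) / (n - 1) else crossprod(a, b) / (n - 1)
}

## cross-covariance between X-block columns and Y advanced by e samples
## (cov(X(t), Y(t + e)) under circular indexing)
.cross_at <- function(Xn, Yn, e) crossprod(Xn, circ_shift(Yn, -e)) / (nrow(Xn) - 1)

## MI between an X block and Y advanced by e, from precomputed within-block
## covariances
.mi_at <- function(Xn, Yn, Sxx, Syy, e) {
  n <- nrow(Xn)
  cr <- .cross_at(Xn, Yn, e)
  p <- ncol(Xn); q <- ncol(Yn)
  C <- rbind(cbind(Sxx, cr), cbind(t(cr), Syy))
  .mi_from_cov(C, n, 1:p, p + 1:q)
}

## CMI(X ; Y advanced by e | Z), X and Z shifted jointly when surrogate
## shifts are folded into e (within-stimulus covariances are shift-invariant)
.cmi_at <- function(Xn, Zn, Yn, Sxx, Szz, Sxz, Syy, e) {
  n <- nrow(Xn)
  crx <- .cross_at(Xn, Yn, e)
  crz <- .cross_at(Zn, Yn, e)
  p <- ncol(Xn); q <- ncol(Yn); r <- ncol(Zn)
  C <- rbind(cbind(Sxx, crx, Sxz),
             cbind(t(crx), Syy, t(crz)),
             cbind(t(Sxz), crz, Szz))
  .cmi_from_cov(C, n, 1:p, p + 1:q, p + q + 1:r)
}

.draw_shifts <- function(reps, n, rate, t_min) {
  smin <- round(t_min * rate)
  if (n < 2L * smin) stop("record too short for surrogate shifts (need at least 2 x t_min)", call. = FALSE)
  sample.int(n - 2L * smin + 1L, reps, replace = TRUE) + smin - 1L
}

#' Randomly time-shift a feature block
#'
#' Applies one circular shift, drawn uniformly from [t_min, T - t_min], to
#' the whole block (all columns jointly), preserving the temporal relation
#' of individual features to each other.  The minimum offset keeps the
#' surrogate outside the autocorrelation range of the slowest band.
#'
#' @param x numeric or complex vector/matrix (time in rows).
#' @param rate sampling rate in Hz (default 50).
#' @param t_min minimum shift in seconds (default 2).
#' @param seed optional integer seed for the draw.
#' @return shifted block with attribute `shift` (samples).
#' @export
random_time_shift <- function(x, rate = 50, t_min = 2, seed = NULL) {
  n <- if (is.matrix(x)) nrow(x) else length(x)
  draw <- function() .draw_shifts(1L, n, rate, t_min)
  s <- if (is.null(seed)) draw() else with_seed(seed, draw())
  out <- circ_shift(x, s)
  attr(out, "shift") <- s
  out
}

#' Bias-matched mutual information
#'
#' Estimates MI(X;Y) as the average over `reps` random time shifts of
#' CMI(X ; Y | X_shifted), where the conditioner is a circularly
#' time-shifted copy of X with no causal relation to Y.  Conditioning on an
#' irrelevant block of the same dimensionality gives the estimate the same
#' small-sample bias as a true CMI, so MI and CMI values are directly
#' comparable.
#'
#' @param x,y vectors or matrices (numeric or complex), samples in rows.
#' @param reps number of shift repetitions (default 2000; scale down for
#'   exploratory runs).
#' @param rate sampling rate in Hz (default 50).
#' @param t_min minimum shift in seconds (default 2).
#' @param seed optional integer seed.
#' @param metadata optional named list attached to the estimate.
#' @return `mi_estimate` of kind `bias_matched_mi`.
#' @export
bias_matched_mi <- function(x, y, reps = 2000, rate = 50, t_min = 2,
                            seed = NULL, metadata = list()) {
  stopifnot(reps >= 1)
  Xn <- copula_normalize(x)
  Yn <- copula_normalize(y)
  n <- nrow(Xn)
  if (nrow(Yn) != n) stop("bias_matched_mi: sample counts differ", call. = FALSE)
  Sxx <- .ncov(Xn); Syy <- .ncov(Yn)
  Sxy <- .ncov(Xn, Yn)
  draw <- function() .draw_shifts(reps, n, rate, t_min)
  shifts <- if (is.null(seed)) draw() else with_seed(seed, draw())
  p <- ncol(Xn); q <- ncol(Yn)
  vals <- vapply(shifts, function(s) {
    Xs <- circ_shift(Xn, s)
    XXs <- .ncov(Xn, Xs)
    YXs <- .ncov(Yn, Xs)
    C <- rbind(cbind(Sxx, Sxy, XXs),
               cbind(t(Sxy), Syy, YXs),
               cbind(t(XXs), t(YXs), Sxx))
    .cmi_from_cov(C, n, 1:p, p + 1:q, p + q + 1:p)
  }, 0)
  .mi_estimate(mean(vals), "bias_matched_mi",
               metadata = c(metadata, list(reps = reps)))
}

#' Subtract a surrogate null baseline from an estimate
#'
#' Computes `estimate_fn(x, y)` minus the mean of `estimate_fn` applied to
#' `reps` randomly time-shifted copies of `x`, rendering independent data
#' approximately zero.
#'
#' @param estimate_fn function of (x, y) returning an `mi_estimate` or a
#'   number (e.g. [gcmi()] or a [bias_matched_mi()] closure).
#' @param x,y data blocks passed to `estimate_fn`.
#' @param reps number of surrogate randomizations (default 100).
#' @param rate,t_min shift parameters as in [random_time_shift()].
#' @param seed optional integer seed.
#' @return `mi_estimate` flagged `baseline_subtracted`, with the baseline
#'   mean and reps in its metadata.
#' @export
null_baseline_subtract <- function(estimate_fn, x, y, reps = 100,
                                   rate = 50, t_min = 2, seed = NULL) {
  val <- function(e) if (inherits(e, "mi_estimate")) e$value else as.numeric(e)
  est <- estimate_fn(x, y)
  n <- if (is.matrix(x)) nrow(x) else length(x)
  draw <- function() .draw_shifts(reps, n, rate, t_min)
  shifts <- if (is.null(seed)) draw() else with_seed(seed, draw())
  base <- mean(vapply(shifts, function(s) val(estimate_fn(circ_shift(x, s), y)), 0))
  kind <- if (inherits(est, "mi_estimate")) est$kind else "mi"
  md <- if (inherits(est, "mi_estimate")) est$metadata else list()
  .mi_estimate(val(est) - base, kind, baseline_subtracted = TRUE,
               metadata = c(md, list(baseline = base, baseline_reps = reps)))
}

#' MI as a function of stimulus-to-brain lag
#'
#' Computes MI between a feature block and a neural channel with the neural
#' signal delayed relative to the features by each lag on the grid
#' (positive lag = brain after stimulus), default 0-500 ms in 20-ms steps.
#'
#' @param features complex or numeric matrix (time x features).
#' @param neural complex or numeric vector/matrix (one channel).
#' @param lags lag grid in seconds (default `seq(0, 0.5, 0.02)`).
#' @param rate sampling rate in Hz (default 50).
#' @return data.frame of class `lag_profile` with columns `lag_s`, `mi`.
#' @export
lag_profile <- function(features, neural, lags = seq(0, 0.5, by = 0.02), rate = 50) {
  Xn <- copula_normalize(features)
  Yn <- copula_normalize(neural)
  n <- nrow(Xn)
  lag_samp <- round(lags * rate)
  if (n <= 2L * max(lag_samp)) stop("lag_profile: record too short for the maximum lag", call. = FALSE)
  Sxx <- .ncov(Xn); Syy <- .ncov(Yn)
  mi <- vapply(lag_samp, function(l) .mi_at(Xn, Yn, Sxx, Syy, l), 0)
  structure(data.frame(lag_s = lags, mi = mi), class = c("lag_profile", "data.frame"))
}

#' Group-level optimal lag
#'
#' Given per-participant, per-condition lag profiles, selects the lag
#' maximizing the group-level MI: profiles are summed over conditions within
#' participant, the median across participants is taken per lag, and the
#' argmax wins (ties broken toward the smaller lag).
#'
#' @param profiles data.frame with columns `participant`, `condition`,
#'   `lag_s`, `mi` (stacked profiles).
#' @return optimal lag in seconds.
#' @export
optimal_lag_group <- function(profiles) {
  stopifnot(nrow(profiles) > 0,
            all(c("participant", "lag_s", "mi") %in% names(profiles)))
  if (!"condition" %in% names(profiles)) profiles$condition <- "all"
  pooled <- stats::aggregate(mi ~ participant + lag_s, data = profiles, FUN = sum)
  med <- stats::aggregate(mi ~ lag_s, data = pooled, FUN = stats::median)
  med <- med[order(med$lag_s), ]
  med$lag_s[which.max(med$mi)]
}

#' Windowed MI around an optimal lag
#'
#' Mean of MI values at lags optimal_lag - window ... + window in
#' `window_step` steps (seven lags by default), clipped to the admissible
#' lag range; the number of in-range lags averaged is recorded.
#'
#' @param features,neural data blocks as in [lag_profile()].
#' @param optimal_lag center lag in seconds.
#' @param window half-window in seconds (default 0.06).
#' @param window_step step in seconds (default 0.02).
#' @param lag_range admissible lag range in seconds (default c(0, 0.5)).
#' @param rate sampling rate (default 50).
#' @param estimator "mi" (plain) or "bias_matched".
#' @param reps repetitions for the bias-matched estimator.
#' @param seed optional seed for the bias-matched shifts.
#' @return `mi_estimate` with `lag` and `n_lags` in its metadata.
#' @export
windowed_mi <- function(features, neural, optimal_lag, window = 0.06,
                        window_step = 0.02, lag_range = c(0, 0.5), rate = 50,
                        estimator = c("mi", "bias_matched"), reps = 2000,
                        seed = NULL) {
  estimator <- match.arg(estimator)
  wl <- seq(optimal_lag - window, optimal_lag + window, by = window_step)
  wl <- wl[wl >= lag_range[1] & wl <= lag_range[2]]
  if (!length(wl)) stop("windowed_mi: no window lags in the admissible range", call. = FALSE)
  vals <- if (estimator == "mi") {
    Xn <- copula_normalize(features)
    Yn <- copula_normalize(neural)
    Sxx <- .ncov(Xn); Syy <- .ncov(Yn)
    vapply(round(wl * rate), function(l) .mi_at(Xn, Yn, Sxx, Syy, l), 0)
  } else {
    vapply(seq_along(wl), function(k) {
      Ys <- circ_shift(as_real_block(neural), -round(wl[k] * rate))
      bias_matched_mi(features, Ys, reps = reps, rate = rate,
                      seed = if (is.null(seed)) NULL else child_seed(seed, k))$value
    }, 0)
  }
  .mi_estimate(mean(vals), if (estimator == "mi") "mi" else "bias_matched_mi",
               metadata = list(lag = optimal_lag, n_lags = length(wl),
                               window_lags = wl))
}

## ---- cohort-level machinery -------------------------------------------

## Band-prepare a cohort: concatenated normalized stimulus block plus
## per-participant/condition/channel normalized neural blocks.
.prep_cohort_band <- function(cohort, band, conditions = c("A", "V"),
                              discard_initial = 0.5) {
  rate <- cohort$cfg$feature_rate
  sp <- prep_band(cohort$features$trials, band, rate, discard_initial)
  Sn <- copula_normalize(sp$analytic)
  feats <- colnames(cohort$features$trials[[1]])
  fidx <- stats::setNames(lapply(seq_along(feats), function(j) c(2L * j - 1L, 2L * j)), feats)
  neural <- list()
  for (p in seq_along(cohort$neural)) {
    neural[[p]] <- list()
    for (cond in conditions) {
      np <- prep_band(cohort$neural[[p]][[cond]], band, rate, discard_initial)
      chs <- colnames(cohort$neural[[p]][[cond]][[1]])
      yl <- lapply(seq_along(chs), function(ci) copula_normalize(np$analytic[, ci]))
      names(yl) <- chs
      neural[[p]][[cond]] <- yl
    }
  }
  list(Sn = Sn, Sxx = .ncov(Sn), fidx = fidx, neural = neural,
       channels = cohort$channels, rate = rate, n = nrow(Sn),
       boundaries = sp$boundaries, band = band)
}

.set_indices <- function(fidx, members) unlist(fidx[members], use.names = FALSE)

#' Track a synthetic or loaded cohort
#'
#' Runs the estimation layer end to end for each band: lag profiles per
#' participant, condition, ROI and feature group; group-level optimal lags;
#' windowed plain MI, bias-matched MI and CMI (partialling the respective
#' other feature group) with surrogate null baselines; and surrogate MI
#' values for the maximum-statistic null.  Optional single features are
#' evaluated at their parent group's optimal lag, with the CMI conditioned
#' on all remaining features.
#'
#' @param cohort a `ct_cohort`.
#' @param bands named list of [band_spec()]s (default the 1-3 Hz band).
#' @param conditions conditions to analyze (default c("A", "V")).
#' @param lags lag grid in seconds.
#' @param window,window_step averaging window around the optimal lag (s).
#' @param reps list with elements `bias_match`, `baseline`, `max_null`
#'   (defaults 2000/100/2000; scale down for exploratory runs).
#' @param single_features optional character vector of individual features
#'   to evaluate (e.g. c("aud_env", "aud_pitch")).
#' @param discard_initial seconds discarded at each trial onset.
#' @param t_min minimum surrogate shift in seconds (default 2).
#' @param seed integer seed governing all surrogate draws.
#' @param verbose print one line per band/participant stage.
#' @return object of class `ct_tracking`: list with `mi_table`,
#'   `surrogates`, `optimal_lags`, `profiles`, `params`.
#' @export
track_cohort <- function(cohort, bands = canonical_bands()["1-3"],
                         conditions = c("A", "V"),
                         lags = seq(0, 0.5, by = 0.02),
                         window = 0.06, window_step = 0.02,
                         reps = list(bias_match = 2000, baseline = 100, max_null = 2000),
                         single_features = NULL,
                         discard_initial = 0.5, t_min = 2,
                         seed = 1L, verbose = FALSE) {
  stopifnot(inherits(cohort, "ct_cohort"))
  grp <- feature_groups()
  rate <- cohort$cfg$feature_rate
  lag_samp <- round(lags * rate)
  n_p <- length(cohort$neural)
  rois <- unique(cohort$channels$roi)
  rows <- list(); surr_rows <- list(); lag_rows <- list(); prof_rows <- list()
  for (bi in seq_along(bands)) {
    band <- bands[[bi]]
    prep <- .prep_cohort_band(cohort, band, conditions, discard_initial)
    n <- prep$n
    if (n <= 2L * max(lag_samp)) stop("track_cohort: record too short for the maximum lag", call. = FALSE)
    Sn <- prep$Sn; Sxx <- prep$Sxx; fidx <- prep$fidx
    if (verbose) message(sprintf("band %s: n=%d samples", band$label, n))
    ## --- lag profiles (group sets, per channel then ROI-averaged) ---
    cross_store <- list()   # [[p]][[cond]][[ch]] : list over lags of 12x2 cross-cov
    prof <- array(0, dim = c(length(lags), length(grp), length(rois), n_p, length(conditions)),
                  dimnames = list(NULL, names(grp), rois, NULL, conditions))
    for (p in seq_len(n_p)) for (ci in seq_along(conditions)) {
      cond <- conditions[ci]
      yl <- prep$neural[[p]][[cond]]
      cross_store[[paste(p, cond)]] <- lapply(yl, function(Yn)
        lapply(lag_samp, function(l) .cross_at(Sn, Yn, l)))
      for (gi in seq_along(grp)) {
        gx <- .set_indices(fidx, grp[[gi]])
        Sg <- Sxx[gx, gx]
        for (ro in rois) {
          chs <- prep$channels$channel[prep$channels$roi == ro]
          acc <- numeric(length(lags))
          for (ch in chs) {
            Yn <- yl[[ch]]
            Syy <- .ncov(Yn)
            crl <- cross_store[[paste(p, cond)]][[ch]]
            acc <- acc + vapply(seq_along(lags), function(li) {
              cr <- crl[[li]][gx, , drop = FALSE]
              C <- rbind(cbind(Sg, cr), cbind(t(cr), Syy))
              .mi_from_cov(C, n, seq_along(gx), length(gx) + 1:2)
            }, 0)
          }
          prof[, gi, ro, p, ci] <- acc / length(chs)
        }
      }
    }
    ## --- group-level optimal lags per (group, roi) ---
    opt <- matrix(0, length(grp), length(rois), dimnames = list(names(grp), rois))
    for (gi in seq_along(grp)) for (ro in rois) {
      df <- do.call(rbind, lapply(seq_len(n_p), function(p)
        do.call(rbind, lapply(seq_along(conditions), function(ci)
          data.frame(participant = p, condition = conditions[ci],
                     lag_s = lags, mi = prof[, gi, ro, p, ci])))))
      opt[gi, ro] <- optimal_lag_group(df)
      lag_rows[[length(lag_rows) + 1L]] <-
        data.frame(band = band$label, feature_set = names(grp)[gi], roi = ro,
                   lag_s = opt[gi, ro])
    }
    for (gi in seq_along(grp)) for (ro in rois) for (p in seq_len(n_p))
      for (ci in seq_along(conditions))
        prof_rows[[length(prof_rows) + 1L]] <-
      data.frame(band = band$label, feature_set = names(grp)[gi], roi = ro,
                 participant = p, condition = conditions[ci],
                 lag_s = lags, mi = prof[, gi, ro, p, ci])
    ## --- analysis sets: groups + optional single features ---
    sets <- lapply(names(grp), function(g)
      list(name = g, members = grp[[g]],
           cond_members = setdiff(unlist(grp), grp[[g]]),
           parent = g))
    for (sf in single_features) {
      parent <- if (sf %in% grp$AudFeat) "AudFeat" else "LipFeat"
      sets[[length(sets) + 1L]] <- list(name = sf, members = sf,
                                        cond_members = setdiff(unlist(grp), sf),
                                        parent = parent)
    }
    ## --- windowed estimates, baselines, surrogates ---
    for (p in seq_len(n_p)) for (ci in seq_along(conditions)) {
      cond <- conditions[ci]
      yl <- prep$neural[[p]][[cond]]
      for (ro in rois) {
        chs <- prep$channels$channel[prep$channels$roi == ro]
        for (set in sets) {
          gx <- .set_indices(fidx, set$members)
          zx <- .set_indices(fidx, set$cond_members)
          Sg <- Sxx[gx, gx]; Sz <- Sxx[zx, zx]; Sgz <- Sxx[gx, zx, drop = FALSE]
          ol <- opt[set$parent, ro]
          wl <- seq(ol - window, ol + window, by = window_step)
          wl <- wl[wl >= min(lags) & wl <= max(lags)]
          wls <- round(wl * rate)
          set_seed_base <- child_seed(seed, bi, p, ci,
                                      match(ro, rois) * 10L + which(vapply(sets, `[[`, "", "name") == set$name))
          shifts_bm <- with_seed(set_seed_base, list(
            bm = .draw_shifts(reps$bias_match, n, rate, t_min),
            base = .draw_shifts(reps$baseline, n, rate, t_min),
            base2 = .draw_shifts(reps$baseline, n, rate, t_min),
            mx = .draw_shifts(reps$max_null, n, rate, t_min)))
          ch_mi <- ch_bm <- ch_cmi <- numeric(length(chs))
          ch_mi_b <- ch_bm_b <- ch_cmi_b <- numeric(length(chs))
          surr_acc <- matrix(0, reps$max_null, length(chs))
          for (k in seq_along(chs)) {
            Yn <- yl[[chs[k]]]
            Syy <- .ncov(Yn)
            Xg <- Sn[, gx, drop = FALSE]; Zg <- Sn[, zx, drop = FALSE]
            ## plain MI + CMI, windowed
            mi_w <- cmi_w <- numeric(length(wls))
            for (li in seq_along(wls)) {
              cr <- .cross_at(Sn, Yn, wls[li])
              crg <- cr[gx, , drop = FALSE]; crz <- cr[zx, , drop = FALSE]
              Cm <- rbind(cbind(Sg, crg), cbind(t(crg), Syy))
              mi_w[li] <- .mi_from_cov(Cm, n, seq_along(gx), length(gx) + 1:2)
              Cc <- rbind(cbind(Sg, crg, Sgz),
                          cbind(t(crg), Syy, t(crz)),
                          cbind(t(Sgz), crz, Sz))
              cmi_w[li] <- .cmi_from_cov(Cc, n, seq_along(gx),
                                         length(gx) + 1:2,
                                         length(gx) + 2L + seq_along(zx))
            }
            ch_mi[k] <- mean(mi_w); ch_cmi[k] <- mean(cmi_w)
            ## bias-matched MI, windowed (shift set shared across window lags)
            Yl_pre <- lapply(wls, function(l) circ_shift(Yn, -l))
            bm_vals <- vapply(shifts_bm$bm, function(s) {
              Xs <- circ_shift(Xg, s)
              XXs <- .ncov(Xg, Xs)
              mean(vapply(seq_along(wls), function(li) {
                YXs <- .ncov(Yl_pre[[li]], Xs)
                C <- rbind(cbind(Sg, t(.ncov(Yl_pre[[li]], Xg)), XXs),
                           cbind(.ncov(Yl_pre[[li]], Xg), Syy, YXs),
                           cbind(t(XXs), t(YXs), Sg))
                .cmi_from_cov(C, n, seq_along(gx), length(gx) + 1:2,
                              length(gx) + 2L + seq_along(gx))
              }, 0))
            }, 0)
            ch_bm[k] <- mean(bm_vals)
            ## baselines (surrogate shifts folded into the effective lag)
            l0 <- round(ol * rate)
            base_mi <- mean(vapply(shifts_bm$base, function(s)
              .mi_at(Xg, Yn, Sg, Syy, l0 + s), 0))
            base_cmi <- mean(vapply(shifts_bm$base, function(s)
              .cmi_at(Xg, Zg, Yn, Sg, Sz, Sgz, Syy, l0 + s), 0))
            base_bm <- mean(vapply(seq_along(shifts_bm$base), function(r) {
              s1 <- shifts_bm$base[r]; s2 <- shifts_bm$base2[r]
              Xs2 <- circ_shift(Xg, s2)
              XXs2 <- .ncov(Xg, Xs2)
              Yl <- circ_shift(Yn, -(l0 + s1))
              C <- rbind(cbind(Sg, t(.ncov(Yl, Xg)), XXs2),
                         cbind(.ncov(Yl, Xg), Syy, .ncov(Yl, circ_shift(Xg, s2))),
                         cbind(t(XXs2), t(.ncov(Yl, circ_shift(Xg, s2))), Sg))
              .cmi_from_cov(C, n, seq_along(gx), length(gx) + 1:2,
                            length(gx) + 2L + seq_along(gx))
            }, 0))
            ch_mi_b[k] <- ch_mi[k] - base_mi
            ch_cmi_b[k] <- ch_cmi[k] - base_cmi
            ch_bm_b[k] <- ch_bm[k] - base_bm
            ## max-null surrogates (plain MI at optimal lag, shifted stimulus)
            surr_acc[, k] <- vapply(shifts_bm$mx, function(s)
              .mi_at(Xg, Yn, Sg, Syy, l0 + s), 0)
          }
          add_row <- function(kind, v, vb, rp) {
            rows[[length(rows) + 1L]] <<-
              data.frame(participant = p, condition = cond, roi = ro,
                         band = band$label, feature_set = set$name, kind = kind,
                         lag_ms = round(ol * 1000), value_bits = mean(v),
                         value_bits_bs = mean(vb), reps = rp, seed = seed)
          }
          add_row("mi", ch_mi, ch_mi_b, reps$baseline)
          add_row("mi_bias_matched", ch_bm, ch_bm_b, reps$bias_match)
          add_row("cmi", ch_cmi, ch_cmi_b, reps$baseline)
          surr_rows[[length(surr_rows) + 1L]] <-
            data.frame(band = band$label, participant = p, condition = cond,
                       roi = ro, feature_set = set$name,
                       value = rowMeans(surr_acc))
        }
      }
      if (verbose) message(sprintf("  participant %d / condition %s done", p, cond))
    }
  }
  structure(list(mi_table = do.call(rbind, rows),
                 surrogates = do.call(rbind, surr_rows),
                 optimal_lags = do.call(rbind, lag_rows),
                 profiles = do.call(rbind, prof_rows),
                 params = list(bands = vapply(bands, `[[`, "", "label"),
                               conditions = conditions, lags = lags,
                               window = window, reps = reps, t_min = t_min,
                               seed = seed)),
            class = "ct_tracking")
}
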