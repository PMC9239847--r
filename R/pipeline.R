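## Orchestration: a single run configuration drives cohort simulation (or
## loading), tracking estimation, group statistics and the brain-behavior
## regression; benchmark drivers measure recovery of planted ground truth.

#' Run configuration
#'
#' Defaults equal the analysis settings used throughout: canonical bands,
#' 0-500 ms lag grid in 20-ms steps, 2000 bias-matching repetitions, 100
#' baseline randomizations, 2000 max-null surrogates, 5000 label
#' permutations, alpha = 0.01.  `test_mode = TRUE` switches to desk-scale
#' repetitions (50/20/200/500) for exploratory runs.
#'
#' @param scenario a [scenario_config()] (synthetic input) or a directory
#'   path for [read_cohort()].
#' @param bands character vector of canonical band labels or list of
#'   [band_spec()]s (default "1-3").
#' @param lags lag grid in seconds.
#' @param window half-window around the optimal lag (s).
#' @param reps list(bias_match, baseline, max_null, label_perm).
#' @param alpha significance level.
#' @param single_features individual features evaluated for the behavior
#'   link (default aud_env and aud_pitch).
#' @param seed integer master seed.
#' @param outdir optional output directory for TSV/JSON reports.
#' @param test_mode reduced-repetition mode.
#' @return object of class `ct_config`.
#' @export
run_config <- function(scenario = scenario_config(),
                       bands = "1-3",
                       lags = seq(0, 0.5, by = 0.02),
                       window = 0.06,
                       reps = list(bias_match = 2000, baseline = 100,
                                   max_null = 2000, label_perm = 5000),
                       alpha = 0.01,
                       single_features = c("aud_env", "aud_pitch"),
                       seed = 1L, outdir = NULL, test_mode = FALSE) {
  if (test_mode) reps <- list(bias_match = 50, baseline = 20,
                              max_null = 200, label_perm = 500)
  if (is.character(bands)) {
    cb <- canonical_bands()
    missing <- setdiff(bands, names(cb))
    if (length(missing)) stop("run_config: unknown band label(s): ",
                              paste(missing, collapse = ", "), call. = FALSE)
    bands <- cb[bands]
  }
  structure(list(scenario = scenario, bands = bands, lags = lags,
                 window = window, reps = reps, alpha = alpha,
                 single_features = single_features, seed = as.integer(seed),
                 outdir = outdir, test_mode = test_mode),
            class = "ct_config")
}

#' Run the tracking pipeline end to end
#'
#' Simulates (or loads) the cohort, runs the estimation layer
#' ([track_cohort()]), builds per-band maximum null distributions, tests
#' group-level medians, compares bias-matched MI against CMI with the
#' max-corrected permutation Wilcoxon test, and fits the brain-behavior
#' partial regression (visual-condition percent correct on envelope/pitch
#' tracking with SNR-proxy confounds).
#'
#' @param config a [run_config()].
#' @return list of class `ct_run`: `mi_table`, `stats_report` (max-null
#'   thresholds, group-median decisions, Wilcoxon comparisons),
#'   `regression` (per band), `optimal_lags`, `config`.
#' @export
run_tracking <- function(config) {
  stopifnot(inherits(config, "ct_config"))
  cohort <- if (inherits(config$scenario, "scenario_config"))
    simulate_cohort(config$scenario) else read_cohort(config$scenario)
  tr <- track_cohort(cohort, bands = config$bands,
                     lags = config$lags, window = config$window,
                     reps = config$reps[c("bias_match", "baseline", "max_null")],
                     single_features = config$single_features,
                     seed = config$seed)
  mt <- tr$mi_table
  grp_names <- names(feature_groups())
  nulls <- build_max_null(tr$surrogates[, c("band", "value")])
  ## group-level median tests (raw values vs raw surrogate null)
  med_rows <- list()
  for (bd in unique(mt$band)) for (kind in c("mi", "cmi"))
    for (cond in unique(mt$condition)) for (ro in unique(mt$roi))
      for (fs in grp_names) {
        v <- mt$value_bits[mt$band == bd & mt$kind == kind & mt$condition == cond &
                             mt$roi == ro & mt$feature_set == fs]
        if (!length(v)) next
        res <- test_group_median(v, nulls[[bd]])
        med_rows[[length(med_rows) + 1L]] <-
          data.frame(band = bd, kind = kind, condition = cond, roi = ro,
                     feature_set = fs, median = res$statistic,
                     threshold = res$threshold, significant = res$significant)
      }
  median_tests <- do.call(rbind, med_rows)
  ## bias-matched MI vs CMI, max-corrected permutation Wilcoxon per band
  wilcox <- list()
  for (bd in unique(mt$band)) {
    cells <- unique(mt[mt$band == bd & mt$feature_set %in% grp_names,
                       c("condition", "roi", "feature_set")])
    lab <- apply(cells, 1, paste, collapse = "|")
    pick <- function(kind, cell)
      mt$value_bits[mt$band == bd & mt$kind == kind &
                      mt$condition == cell[1] & mt$roi == cell[2] &
                      mt$feature_set == cell[3]]
    a <- sapply(seq_len(nrow(cells)), function(i) pick("mi_bias_matched", unlist(cells[i, ])))
    b <- sapply(seq_len(nrow(cells)), function(i) pick("cmi", unlist(cells[i, ])))
    colnames(a) <- colnames(b) <- lab
    wilcox[[bd]] <- permutation_wilcoxon_paired(a, b,
                                                n_perm = config$reps$label_perm,
                                                alpha = config$alpha,
                                                seed = child_seed(config$seed, 97L))
  }
  ## brain-behavior partial regression per band
  regression <- .behavior_link(mt, cohort, config)
  out <- structure(list(mi_table = mt,
                        stats_report = list(
                          max_null_thresholds = vapply(nulls, `[[`, 0, "threshold"),
                          median_tests = median_tests,
                          wilcoxon_mi_vs_cmi = wilcox,
                          alpha = config$alpha, seed = config$seed),
                        regression = regression,
                        optimal_lags = tr$optimal_lags,
                        config = config),
                   class = "ct_run")
  if (!is.null(config$outdir)) .write_run(out, config$outdir)
  out
}

.behavior_link <- function(mt, cohort, config) {
  if (!all(c("aud_env", "aud_pitch") %in% config$single_features)) return(NULL)
  bh <- cohort$behavior
  pc_v <- bh$pc[bh$condition == "V"][order(bh$participant[bh$condition == "V"])]
  bands <- unique(mt$band)
  get_vals <- function(bd, fs, ro, cond, kind = "mi") {
    sel <- mt$band == bd & mt$feature_set == fs & mt$roi == ro &
      mt$condition == cond & mt$kind == kind
    mt$value_bits_bs[sel][order(mt$participant[sel])]
  }
  ## SNR-proxy confounds: z-scored per band, averaged across bands
  conf_lip <- zscore_bands_average(sapply(bands, function(bd)
    get_vals(bd, "LipFeat", "occipital", "V")))
  conf_aud <- zscore_bands_average(sapply(bands, function(bd)
    get_vals(bd, "AudFeat", "temporal", "A")))
  out <- list()
  for (bd in bands) {
    df <- data.frame(pc = pc_v,
                     mi_env_temporal = get_vals(bd, "aud_env", "temporal", "V"),
                     mi_pitch_occipital = get_vals(bd, "aud_pitch", "occipital", "V"),
                     conf_lip = conf_lip, conf_aud = conf_aud)
    out[[bd]] <- tryCatch(
      partial_regression(df, "pc",
                         targets = c("mi_env_temporal", "mi_pitch_occipital"),
                         confounds = c("conf_lip", "conf_aud"),
                         confounds_standardized = TRUE),
      error = function(e) structure(list(error = conditionMessage(e)),
                                    class = "ct_regression_error"))
  }
  out
}

.write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(run$mi_table, file.path(outdir, "mi_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$optimal_lags, file.path(outdir, "optimal_lags.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sr <- run$stats_report
  sr$wilcoxon_mi_vs_cmi <- lapply(sr$wilcoxon_mi_vs_cmi, function(w)
    c(as.list(w), list(threshold = attr(w, "threshold"))))
  jsonlite::write_json(sr, file.path(outdir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  reg <- lapply(run$regression, function(r)
    if (inherits(r, "ct_regression"))
      list(coefficients = r$coefficients, r_squared = r$r_squared,
           bf_targets = r$bf_targets) else r)
  jsonlite::write_json(reg, file.path(outdir, "regression.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(outdir)
}

## ---- benchmark drivers -------------------------------------------------

## Lean single-condition group analysis: per-participant ROI-averaged
## windowed value (MI or CMI given the complementary set) at the
## group-optimal lag, plus surrogate values at random circular shifts.
.lean_group_stat <- function(cohort, band, condition, roi, members,
                             cond_members = NULL,
                             lags = seq(0, 0.5, by = 0.02),
                             window = 0.06, reps_surr = 12, t_min = 2,
                             seed = 1L, prep = NULL) {
  if (is.null(prep)) prep <- .prep_cohort_band(cohort, band, condition)
  n <- prep$n; rate <- prep$rate
  Sn <- prep$Sn; Sxx <- prep$Sxx; fidx <- prep$fidx
  gx <- .set_indices(fidx, members)
  zx <- if (is.null(cond_members)) integer(0) else .set_indices(fidx, cond_members)
  Sg <- Sxx[gx, gx]
  chs <- prep$channels$channel[prep$channels$roi == roi]
  n_p <- length(prep$neural)
  lag_samp <- round(lags * rate)
  Xg <- Sn[, gx, drop = FALSE]
  Zg <- if (length(zx)) Sn[, zx, drop = FALSE] else NULL
  Sz <- if (length(zx)) Sxx[zx, zx] else NULL
  Sgz <- if (length(zx)) Sxx[gx, zx, drop = FALSE] else NULL
  val_at <- function(Yn, Syy, e) {
    if (length(zx)) .cmi_at(Xg, Zg, Yn, Sg, Sz, Sgz, Syy, e)
    else .mi_at(Xg, Yn, Sg, Syy, e)
  }
  ## lag selection always uses the plain MI profile of the feature set;
  ## conditional values are then evaluated at that lag (selecting the lag
  ## on the CMI itself would, under the null, favor misaligned
  ## conditioners and inflate leakage)
  profiles <- matrix(0, length(lags), n_p)
  Ys <- Syys <- vector("list", n_p)
  for (p in seq_len(n_p)) {
    yl <- prep$neural[[p]][[condition]][chs]
    Syy_l <- lapply(yl, .ncov)
    profiles[, p] <- rowMeans(sapply(seq_along(yl), function(k)
      vapply(lag_samp, function(l) .mi_at(Xg, yl[[k]], Sg, Syy_l[[k]], l), 0)))
    Ys[[p]] <- yl; Syys[[p]] <- Syy_l
  }
  med <- apply(profiles, 1, stats::median)
  opt_i <- which.max(med)
  l0 <- lag_samp[opt_i]
  wl <- lag_samp[abs(lag_samp - l0) <= round(window * rate) + 1e-9]
  observed <- vapply(seq_len(n_p), function(p)
    mean(sapply(seq_along(Ys[[p]]), function(k)
      mean(vapply(wl, function(l) val_at(Ys[[p]][[k]], Syys[[p]][[k]], l), 0)))), 0)
  surr <- matrix(0, reps_surr, n_p)
  for (p in seq_len(n_p)) {
    shifts <- with_seed(child_seed(seed, 31L, p), .draw_shifts(reps_surr, n, rate, t_min))
    surr[, p] <- vapply(shifts, function(s)
      mean(vapply(seq_along(Ys[[p]]), function(k)
        val_at(Ys[[p]][[k]], Syys[[p]][[k]], l0 + s), 0)), 0)
  }
  list(observed = observed, surrogates = as.numeric(surr),
       optimal_lag = lags[opt_i], profiles = profiles, prep = prep)
}

#' Family-wise false-positive calibration of the max-null median test
#'
#' Simulates cohorts with all tracking gains set to zero (global null),
#' runs the tracking and max-null group-median machinery over a scope of
#' ROI x feature-group cells in the visual condition, and reports the
#' family-wise false-positive rate.
#'
#' @param n_replicates number of null cohorts (default 200).
#' @param n_participants,n_trials cohort size (defaults 18 and 60).
#' @param reps_surr surrogates per participant and cell (default 12).
#' @param band analysis band (default 1-3 Hz).
#' @param alpha nominal level (via the 99th-percentile threshold).
#' @param seed master seed.
#' @return list with `fwer`, `se`, `rejections` (per-replicate flags).
#' @export
benchmark_null_calibration <- function(n_replicates = 200, n_participants = 18,
                                       n_trials = 60, reps_surr = 12,
                                       band = canonical_bands()[["1-3"]],
                                       alpha = 0.01, seed = 1L) {
  rej <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- scenario_config(n_participants = n_participants, n_trials = n_trials,
                           gains = stats::setNames(rep(0, 6), feature_names()),
                           n_channels = 1L,
                           seed = child_seed(seed, 41L, r))
    rej[r] <- .null_calibration_replicate(cfg, band, reps_surr,
                                          seed = child_seed(seed, 42L, r))
  }
  fwer <- mean(rej)
  list(fwer = fwer, se = sqrt(fwer * (1 - fwer) / n_replicates),
       nominal = alpha, rejections = rej)
}

## One global-null replicate: lag profiles / windowed MI / surrogates for
## all four ROI x feature-group cells, sharing the stimulus cross-covariance
## across groups, then the pooled max-null group-median decision.
.null_calibration_replicate <- function(cfg, band, reps_surr, seed,
                                        lags = seq(0, 0.5, by = 0.02),
                                        window = 0.06, t_min = 2) {
  grp <- feature_groups()
  cohort <- simulate_cohort(cfg, conditions = "V")
  prep <- .prep_cohort_band(cohort, band, "V")
  n <- prep$n; rate <- prep$rate
  Sn <- prep$Sn; Sxx <- prep$Sxx
  gidx <- lapply(grp, function(m) .set_indices(prep$fidx, m))
  Sg <- lapply(gidx, function(ix) Sxx[ix, ix])
  lag_samp <- round(lags * rate)
  n_p <- length(prep$neural)
  rois <- unique(prep$channels$roi)
  chs_by_roi <- split(prep$channels$channel, prep$channels$roi)[rois]
  ## profiles[lag, participant, roi, group]; the 26 lag-advanced copies of
  ## each channel are batched into one crossprod
  nl <- length(lag_samp)
  idx_adv <- sapply(lag_samp, function(e) if (e == 0L) seq_len(n) else c((e + 1L):n, seq_len(e)))
  prof <- array(0, dim = c(nl, n_p, length(rois), length(grp)))
  crosses <- vector("list", n_p)
  for (p in seq_len(n_p)) {
    crosses[[p]] <- list()
    for (ri in seq_along(rois)) {
      yl <- prep$neural[[p]][["V"]][chs_by_roi[[ri]]]
      for (k in seq_along(yl)) {
        Yn <- yl[[k]]; Syy <- .ncov(Yn)
        Yb <- cbind(matrix(Yn[as.vector(idx_adv), 1L], n, nl),
                    matrix(Yn[as.vector(idx_adv), 2L], n, nl))
        crb <- crossprod(Sn, Yb) / (n - 1)
        crosses[[p]][[rois[ri]]][[k]] <- list(Yn = Yn, Syy = Syy)
        for (gi in seq_along(grp)) {
          ix <- gidx[[gi]]
          prof[, p, ri, gi] <- prof[, p, ri, gi] +
            vapply(seq_len(nl), function(li) {
              cr <- crb[ix, c(li, nl + li), drop = FALSE]
              C <- rbind(cbind(Sg[[gi]], cr), cbind(t(cr), Syy))
              .mi_from_cov(C, n, seq_along(ix), length(ix) + 1:2)
            }, 0) / length(yl)
        }
      }
    }
  }
  observed <- surr <- list()
  for (ri in seq_along(rois)) for (gi in seq_along(grp)) {
    cell <- paste(rois[ri], names(grp)[gi])
    med <- apply(prof[, , ri, gi, drop = FALSE], 1, stats::median)
    l0 <- lag_samp[which.max(med)]
    win <- abs(lag_samp - l0) <= round(window * rate) + 1e-9
    observed[[cell]] <- colMeans(prof[win, , ri, gi, drop = FALSE][, , 1, 1])
    Xg <- Sn[, gidx[[gi]], drop = FALSE]
    pg <- ncol(Xg)
    sv <- matrix(0, reps_surr, n_p)
    for (p in seq_len(n_p)) {
      shifts <- with_seed(child_seed(seed, 43L, ri, gi, p),
                          .draw_shifts(reps_surr, n, rate, t_min))
      yy <- crosses[[p]][[rois[ri]]]
      acc <- numeric(reps_surr)
      for (ch in yy) {
        idx <- unlist(lapply((l0 + shifts) %% n, function(e)
          if (e == 0L) seq_len(n) else c((e + 1L):n, seq_len(e))))
        Yb <- cbind(matrix(ch$Yn[idx, 1L], n, reps_surr),
                    matrix(ch$Yn[idx, 2L], n, reps_surr))
        crb <- crossprod(Xg, Yb) / (n - 1)
        acc <- acc + vapply(seq_len(reps_surr), function(r2) {
          cr <- crb[, c(r2, reps_surr + r2), drop = FALSE]
          C <- rbind(cbind(Sg[[gi]], cr), cbind(t(cr), ch$Syy))
          .mi_from_cov(C, n, seq_len(pg), pg + 1:2)
        }, 0)
      }
      sv[, p] <- acc / length(yy)
    }
    surr[[cell]] <- as.numeric(sv)
  }
  pooled <- unlist(surr)
  null <- build_max_null(pooled, n_keep = min(2000L, length(pooled)))
  any(vapply(observed, function(v) test_group_median(v, null)$significant, TRUE))
}

#' Lag recovery benchmark
#'
#' Simulates cohorts with a planted stimulus-to-brain lag and checks that
#' the group-level lag search recovers it within one 20-ms grid step.
#'
#' @param n_cohorts number of seeded cohorts (default 20).
#' @param lags_true planted lags in seconds, cycled over cohorts.
#' @param n_participants,n_trials cohort size (defaults 8 and 30).
#' @param snr signal-to-noise variance ratio (default 6, the high-snr
#'   regime).
#' @param band analysis band.
#' @param seed master seed.
#' @return data.frame (cohort, true_lag, recovered_lag, hit) with the
#'   recovery rate as attribute `rate`.
#' @export
benchmark_lag_recovery <- function(n_cohorts = 20,
                                   lags_true = c(0.06, 0.10, 0.14),
                                   n_participants = 8, n_trials = 30,
                                   snr = 6,
                                   band = canonical_bands()[["0.5-8"]],
                                   seed = 1L) {
  rows <- lapply(seq_len(n_cohorts), function(r) {
    lt <- lags_true[(r - 1L) %% length(lags_true) + 1L]
    cfg <- scenario_config(n_participants = n_participants, n_trials = n_trials,
                           tracking_lag = lt, snr = snr,
                           seed = child_seed(seed, 51L, r))
    cohort <- simulate_cohort(cfg, conditions = "A")
    st <- .lean_group_stat(cohort, band, "A", "temporal",
                           feature_groups()$AudFeat, reps_surr = 2,
                           seed = child_seed(seed, 52L, r))
    data.frame(cohort = r, true_lag = lt, recovered_lag = st$optimal_lag,
               hit = abs(st$optimal_lag - lt) <= 0.02 + 1e-9)
  })
  out <- do.call(rbind, rows)
  attr(out, "rate") <- mean(out$hit)
  out
}

#' Restoration-detection benchmark
#'
#' For cohorts with and without cross-modal leak, tests whether the
#' conditional tracking of acoustic features given lip features in
#' visual-condition occipital channels is significant against the
#' surrogate max-null at alpha = 0.01.  Detection should occur when leak
#' is positive and not when it is zero.
#'
#' @param n_seeds cohorts per leak level (default 10).
#' @param leaks leak levels (default c(0, 0.6)).
#' @param snr signal-to-noise ratio (default 4).
#' @param n_participants,n_trials cohort size (defaults 12 and 40).
#' @param reps_surr surrogates per participant (default 15).
#' @param seed master seed.
#' @return data.frame (leak, seed_index, significant) with detection rates
#'   per leak level as attribute `rates`.
#' @export
benchmark_restoration <- function(n_seeds = 10, leaks = c(0, 0.6), snr = 4,
                                  n_participants = 12, n_trials = 40,
                                  reps_surr = 15,
                                  band = canonical_bands()[["1-3"]],
                                  seed = 1L) {
  grp <- feature_groups()
  rows <- list()
  for (lk in leaks) for (r in seq_len(n_seeds)) {
    cfg <- scenario_config(n_participants = n_participants, n_trials = n_trials,
                           leak = lk, snr = snr,
                           seed = child_seed(seed, 61L, round(100 * lk), r))
    cohort <- simulate_cohort(cfg, conditions = "V")
    st <- .lean_group_stat(cohort, band, "V", "occipital",
                           grp$AudFeat, cond_members = grp$LipFeat,
                           reps_surr = reps_surr,
                           seed = child_seed(seed, 62L, round(100 * lk), r))
    null <- build_max_null(st$surrogates,
                           n_keep = min(2000L, length(st$surrogates)))
    rows[[length(rows) + 1L]] <-
      data.frame(leak = lk, seed_index = r,
                 median_cmi = stats::median(st$observed),
                 threshold = null$threshold,
                 significant = test_group_median(st$observed, null)$significant)
  }
  out <- do.call(rbind, rows)
  attr(out, "rates") <- tapply(out$significant, out$leak, mean)
  out
}

#' Behavior-link recovery benchmark
#'
#' Generates behavioral scores coupled to the planted per-participant
#' tracking gain (beta in s.d. units) and fits the partial regression of
#' percent correct on the z-scored gain plus an orthogonal control
#' predictor.  Reports the mean recovered standardized coefficient and the
#' control's type-I rate at alpha = 0.05.
#'
#' @param n_seeds seeds for coefficient recovery (default 500).
#' @param n_seeds_type1 seeds for the control calibration (default 2000).
#' @param beta planted coupling (default 0.6).
#' @param n_participants participants per cohort (default 18).
#' @param seed master seed.
#' @return list with `beta_hat_mean`, `beta_hats`, `type1_rate`.
#' @export
benchmark_behavior_recovery <- function(n_seeds = 500, n_seeds_type1 = 2000,
                                        beta = 0.6, n_participants = 18,
                                        seed = 1L) {
  one <- function(r) {
    cfg <- scenario_config(n_participants = n_participants,
                           behavior_beta = beta,
                           seed = child_seed(seed, 71L, r))
    gm <- with_seed(child_seed(cfg$seed, 73L),
                    exp(stats::rnorm(n_participants, 0, cfg$gain_multiplier_sd)))
    bh <- generate_behavior(list(gain_multiplier = gm), cfg)
    df <- data.frame(pc = bh$pc[bh$condition == "V"],
                     gain = log(gm),
                     control = with_seed(child_seed(cfg$seed, 72L),
                                         stats::rnorm(n_participants)))
    fit <- partial_regression(df, "pc", targets = c("gain", "control"))
    cf <- fit$coefficients
    c(beta_hat = cf$beta[cf$term == "gain"], p_control = cf$p[cf$term == "control"])
  }
  rec <- vapply(seq_len(n_seeds), one, c(beta_hat = 0, p_control = 0))
  type1 <- vapply(seq_len(n_seeds_type1), function(r)
    one(10000L + r)["p_control"] < 0.05, TRUE)
  list(beta_hat_mean = mean(rec["beta_hat", ]),
       beta_hats = rec["beta_hat", ],
       type1_rate = mean(type1))
}

#' Sweep leak / snr / lag grids and summarize recovery
#'
#' Runs one small cohort per grid point and seed, recording the lag-search
#' error and whether conditional acoustic tracking in visual-condition
#' occipital channels is detected.
#'
#' @param sweep named list with numeric vectors `leak`, `snr`, `lag`.
#' @param seeds integer vector of cohort seeds.
#' @param n_participants,n_trials cohort size per run.
#' @param reps_surr surrogates per participant for the detection test.
#' @param band analysis band.
#' @return data.frame with one row per grid point x seed (lag error in s,
#'   detection flag).
#' @export
run_benchmark <- function(sweep = list(leak = c(0, 0.6), snr = c(4), lag = c(0.1)),
                          seeds = 1:3, n_participants = 8, n_trials = 30,
                          reps_surr = 12,
                          band = canonical_bands()[["1-3"]]) {
  if (!length(sweep) || any(!vapply(sweep, length, 0L)))
    stop("run_benchmark: empty sweep", call. = FALSE)
  stopifnot(all(c("leak", "snr", "lag") %in% names(sweep)))
  grid <- expand.grid(leak = sweep$leak, snr = sweep$snr, lag = sweep$lag,
                      seed = seeds)
  grp <- feature_groups()
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    cfg <- scenario_config(n_participants = n_participants, n_trials = n_trials,
                           leak = g$leak, snr = g$snr, tracking_lag = g$lag,
                           seed = child_seed(g$seed, 81L, i))
    cohort <- simulate_cohort(cfg, conditions = c("A", "V"))
    lag_st <- .lean_group_stat(cohort, canonical_bands()[["0.5-8"]], "A",
                               "temporal", grp$AudFeat,
                               reps_surr = 2, seed = child_seed(g$seed, 82L, i))
    res_st <- .lean_group_stat(cohort, band, "V", "occipital", grp$AudFeat,
                               cond_members = grp$LipFeat,
                               reps_surr = reps_surr,
                               seed = child_seed(g$seed, 83L, i))
    null <- build_max_null(res_st$surrogates,
                           n_keep = min(2000L, length(res_st$surrogates)))
    data.frame(leak = g$leak, snr = g$snr, lag = g$lag, seed = g$seed,
               recovered_lag = lag_st$optimal_lag,
               lag_error = abs(lag_st$optimal_lag - g$lag),
               restoration_detected = test_group_median(res_st$observed, null)$significant)
  })
  do.call(rbind, rows)
}
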