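## Synthetic cohort generator with known ground truth: six stimulus features
## as filtered Gaussian processes sharing a latent component (so the
## envelope/lip-area coherence is set analytically), pseudo-neural channels
## that track delayed features over 1/f background noise, and behavioral
## scores coupled to each participant's planted tracking gain.

#' Scenario configuration for synthetic cohorts
#'
#' Defaults emulate the study conditions: 18 participants, 180
#' sentence-trials of duration Normal(5.4, 0.4) s truncated to [4.6, 6.5] s,
#' features at 50 Hz, envelope/lip-area band coherence 0.2, stimulus-to-brain
#' lags on the 60-140 ms grid, and four-choice word-recognition scores with
#' chance level 0.25.
#'
#' @param n_participants number of participants (default 18).
#' @param n_trials number of sentence trials (default 180).
#' @param trial_duration mean trial duration in s (default 5.4).
#' @param trial_duration_sd s.d. of trial duration (default 0.4).
#' @param trial_duration_range truncation range in s (default c(4.6, 6.5)).
#' @param feature_rate feature/neural sampling rate in Hz (default 50).
#' @param coherence_target target envelope/lip-area magnitude-squared
#'   coherence, in [0, 1) (default 0.2).
#' @param tracking_lag per-participant true lag range in s (default
#'   c(0.06, 0.14)); a scalar fixes the lag for all participants.  Lags snap
#'   to the 20-ms grid.
#' @param gains named per-feature tracking gains (see default); scale by
#'   `gain_multiplier_sd` per participant.
#' @param gain_multiplier_sd s.d. of the log-normal per-participant gain
#'   multiplier (default 0.3).
#' @param leak strength with which unheard acoustic features drive the
#'   "V-only" channels (default 0 = no cross-modal restoration).
#' @param snr signal-to-noise variance ratio of driven channels (default 1).
#' @param n_channels channels per ROI (temporal, occipital; default 2).
#' @param behavior_beta coupling (in s.d. units) of percent-correct to the
#'   z-scored planted tracking gain (default 0.6).
#' @param behavior_base named baseline percent-correct per condition
#'   (default c(A = 0.70, V = 0.71)).
#' @param behavior_scale maps percent-correct z-units to the proportion
#'   scale (default 0.1).
#' @param seed integer; fully determines the cohort.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(n_participants = 18L, n_trials = 180L,
                            trial_duration = 5.4, trial_duration_sd = 0.4,
                            trial_duration_range = c(4.6, 6.5),
                            feature_rate = 50,
                            coherence_target = 0.2,
                            tracking_lag = c(0.06, 0.14),
                            gains = c(aud_env = 1, aud_slope = 0.5, aud_pitch = 0.7,
                                      lip_area = 1, lip_slope = 0.5, lip_width = 0.7),
                            gain_multiplier_sd = 0.3,
                            leak = 0, snr = 1, n_channels = 2L,
                            behavior_beta = 0.6,
                            behavior_base = c(A = 0.70, V = 0.71),
                            behavior_scale = 0.1,
                            seed = 1L) {
  if (!is.numeric(coherence_target) || coherence_target < 0 || coherence_target >= 1)
    stop("scenario_config: coherence_target must be in [0, 1)", call. = FALSE)
  if (feature_rate <= 0) stop("scenario_config: feature_rate must be positive", call. = FALSE)
  if (any(tracking_lag < 0)) stop("scenario_config: tracking_lag must be nonnegative", call. = FALSE)
  stopifnot(length(trial_duration_range) == 2, trial_duration_range[1] < trial_duration_range[2])
  miss <- setdiff(feature_names(), names(gains))
  if (length(miss)) stop("scenario_config: gains missing for ", paste(miss, collapse = ", "), call. = FALSE)
  structure(list(n_participants = as.integer(n_participants),
                 n_trials = as.integer(n_trials),
                 trial_duration = trial_duration,
                 trial_duration_sd = trial_duration_sd,
                 trial_duration_range = trial_duration_range,
                 feature_rate = feature_rate,
                 coherence_target = coherence_target,
                 tracking_lag = tracking_lag,
                 gains = gains[feature_names()],
                 gain_multiplier_sd = gain_multiplier_sd,
                 leak = leak, snr = snr,
                 n_channels = as.integer(n_channels),
                 behavior_beta = behavior_beta,
                 behavior_base = behavior_base,
                 behavior_scale = behavior_scale,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

## 1/f-shaped band-limited Gaussian noise, unit variance per column:
## amplitude ~ (f + 0.3)^-1/2 up to 7 Hz, cosine roll-off to zero at 10 Hz.
.shaped_noise <- function(n, ncols) {
  m <- stats::nextn(n, c(2, 3, 5))   # FFT-friendly length; excess truncated
  k <- seq_len(m) - 1L
  f <- pmin(k, m - k) * 50 / m
  amp <- ifelse(f > 0 & f <= 10, (f + 0.3)^(-0.5), 0)
  roll <- f > 7 & f <= 10
  amp[roll] <- amp[roll] * 0.5 * (1 + cos(pi * (f[roll] - 7) / 3))
  amp <- amp / sqrt(mean(amp^2))
  w <- matrix(stats::rnorm(m * ncols), m, ncols)
  out <- Re(stats::mvfft(stats::mvfft(w) * amp, inverse = TRUE) / m)
  out[seq_len(n), , drop = FALSE]
}

.draw_durations <- function(cfg) {
  with_seed(child_seed(cfg$seed, 1L), {
    out <- numeric(cfg$n_trials)
    for (k in seq_len(cfg$n_trials)) {
      repeat {
        d <- stats::rnorm(1, cfg$trial_duration, cfg$trial_duration_sd)
        if (d >= cfg$trial_duration_range[1] && d <= cfg$trial_duration_range[2]) break
      }
      out[k] <- d
    }
    out
  })
}

#' Generate the six stimulus feature streams for a cohort
#'
#' Features are band-limited (< 10 Hz) Gaussian processes with 1/f-shaped
#' spectra.  The envelope and lip-area draw on a shared latent component
#' with mixing weight solved analytically from `coherence_target`
#' (coherence = weight^4 / total-variance^2, so weight^2 =
#' sqrt(coherence_target)); pitch and lip width share the latent weakly.
#' Nonnegative features are obtained by offsetting and soft-rectifying,
#' which is harmless to the rank-based copula downstream.  `aud_slope` and
#' `lip_slope` are exactly the first differences of `aud_env` and
#' `lip_area`.
#'
#' @param cfg a [scenario_config()].
#' @return object of class `ct_features`: list with `trials` (list of
#'   time x 6 matrices, named columns), `durations` (s), `rate`.
#' @export
generate_feature_streams <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  durations <- .draw_durations(cfg)
  a <- sqrt(cfg$coherence_target)   # latent weight^2 for env & lip area
  b_pitch <- 0.1; b_width <- 0.3    # weak latent sharing for realism
  trials <- vector("list", cfg$n_trials)
  for (k in seq_len(cfg$n_trials)) {
    n <- round(durations[k] * cfg$feature_rate)
    z <- with_seed(child_seed(cfg$seed, 2L, k), .shaped_noise(n, 5L))
    env_z <- sqrt(a) * z[, 1] + sqrt(1 - a) * z[, 2]
    lip_z <- sqrt(a) * z[, 1] + sqrt(1 - a) * z[, 3]
    pitch_z <- sqrt(b_pitch) * z[, 1] + sqrt(1 - b_pitch) * z[, 4]
    width_z <- sqrt(b_width) * z[, 1] + sqrt(1 - b_width) * z[, 5]
    env <- softplus(env_z + 3)
    area <- softplus(lip_z + 3)
    m <- cbind(aud_env = env,
               aud_slope = c(0, diff(env)),
               aud_pitch = 75 + 15 * softplus(pitch_z + 3),
               lip_area = area,
               lip_slope = c(0, diff(area)),
               lip_width = softplus(width_z + 3))
    trials[[k]] <- m
  }
  structure(list(trials = trials, durations = durations, rate = cfg$feature_rate),
            class = "ct_features")
}

## 1/f background noise for one participant x condition: drawn as a single
## shaped record over the whole session and split at trial boundaries (one
## child seed per participant, so a participant can be regenerated alone)
.noise_trials <- function(cfg, p, ci, trial_lens, n_ch) {
  total <- sum(trial_lens)
  nz <- with_seed(child_seed(cfg$seed, 4L, p, ci), .shaped_noise(total, n_ch))
  ends <- cumsum(trial_lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_along(trial_lens), function(k)
    nz[starts[k]:ends[k], , drop = FALSE])
}

## per-trial standardized feature matrix (zero mean, unit sd per column)
.std_features <- function(m) {
  sweep(sweep(m, 2L, colMeans(m)), 2L, apply(m, 2L, stats::sd), "/")
}

#' Generate entrained pseudo-neural channels
#'
#' Each driven channel is a gain-weighted sum of delayed (integer-sample,
#' 20-ms grid) standardized features plus 1/f background noise, scaled so
#' the signal/noise variance ratio equals `snr`.  In "A" (audio-only)
#' trials, temporal-ROI channels are driven by the acoustic features; in
#' "V" (visual-only) trials, occipital channels are driven by the lip
#' features plus `leak` times the acoustic features, and temporal channels
#' by `leak` times the acoustic features alone (the restoration pathway).
#' Undriven channels are pure noise.
#'
#' @param features a `ct_features` object from [generate_feature_streams()].
#' @param cfg the same [scenario_config()].
#' @param conditions conditions to generate (default c("A", "V")).
#' @return list with `neural` (per participant, per condition, list of
#'   time x channel matrices), `channels` (data.frame channel/roi) and
#'   `ground_truth` (planted lags, gain multipliers, leak, snr).
#' @export
generate_neural <- function(features, cfg, conditions = c("A", "V")) {
  stopifnot(inherits(features, "ct_features"), inherits(cfg, "scenario_config"))
  rate <- cfg$feature_rate
  grid <- 1 / rate * round(seq(min(cfg$tracking_lag), max(cfg$tracking_lag), by = 0.02) * rate)
  min_len <- min(vapply(features$trials, nrow, 0L))
  if (round(max(grid) * rate) >= min_len)
    stop("generate_neural: tracking lag exceeds trial duration", call. = FALSE)
  grp <- feature_groups()
  ch_names <- c(paste0("temporal_", seq_len(cfg$n_channels)),
                paste0("occipital_", seq_len(cfg$n_channels)))
  channels <- data.frame(channel = ch_names,
                         roi = rep(c("temporal", "occipital"), each = cfg$n_channels))
  lags <- numeric(cfg$n_participants)
  mult <- numeric(cfg$n_participants)
  neural <- vector("list", cfg$n_participants)
  all_null <- all(cfg$gains == 0) && cfg$leak == 0
  std_tr <- if (all_null) features$trials else lapply(features$trials, .std_features)
  for (p in seq_len(cfg$n_participants)) {
    with_seed(child_seed(cfg$seed, 3L, p), {
      lags[p] <- if (length(grid) == 1L) grid else sample(grid, 1L)
      mult[p] <- exp(stats::rnorm(1, 0, cfg$gain_multiplier_sd))
    })
    lag_samp <- round(lags[p] * rate)
    g <- cfg$gains * mult[p]
    null_gains <- all(cfg$gains == 0) && cfg$leak == 0
    drive <- function(tr, feats, scale = 1) {
      s <- numeric(nrow(tr))
      for (f in feats) s <- s + scale * g[f] * circ_shift(tr[, f], lag_samp)
      s
    }
    per_cond <- list()
    for (cond in conditions) {
      ci <- match(cond, c("A", "V"))
      noise_tr <- .noise_trials(cfg, p, ci, vapply(std_tr, nrow, 0L), length(ch_names))
      if (null_gains) {
        ## pure-noise channels: skip the drive computation entirely
        per_cond[[cond]] <- lapply(noise_tr, function(nz) {
          colnames(nz) <- ch_names
          nz
        })
        next
      }
      sig <- lapply(std_tr, function(tr) {
        out <- matrix(0, nrow(tr), length(ch_names), dimnames = list(NULL, ch_names))
        for (ci in seq_len(nrow(channels))) {
          s <- numeric(nrow(tr))
          if (cond == "A" && channels$roi[ci] == "temporal")
            s <- drive(tr, grp$AudFeat)
          if (cond == "V" && channels$roi[ci] == "occipital")
            s <- drive(tr, grp$LipFeat) + drive(tr, grp$AudFeat, cfg$leak)
          if (cond == "V" && channels$roi[ci] == "temporal")
            s <- drive(tr, grp$AudFeat, cfg$leak)
          out[, ci] <- s
        }
        out
      })
      sig_var <- apply(do.call(rbind, sig), 2L, stats::var)
      sigma <- ifelse(sig_var > 0, sqrt(sig_var / cfg$snr), 1)
      per_cond[[cond]] <- lapply(seq_along(sig), function(k) {
        out <- sig[[k]] + sweep(noise_tr[[k]], 2L, sigma, "*")
        colnames(out) <- ch_names
        out
      })
    }
    neural[[p]] <- per_cond
  }
  list(neural = neural, channels = channels,
       ground_truth = list(lags = lags, gain_multiplier = mult,
                           gains = cfg$gains, leak = cfg$leak, snr = cfg$snr))
}

#' Generate behavioral word-recognition scores
#'
#' Percent-correct per participant and condition:
#' base + scale * (beta * z(gain) + sqrt(1 - beta^2) * noise), clipped to
#' [0.25, 1] (chance level of the four-choice task).  With `behavior_beta`
#' in [0, 1] the z-scored score has unit variance before clipping, so a
#' standardized regression on the z-scored planted gain recovers `beta`.
#'
#' @param ground_truth ground-truth list from [generate_neural()].
#' @param cfg the [scenario_config()].
#' @return data.frame (participant, condition, pc) plus attribute
#'   `generative_mean`.
#' @export
generate_behavior <- function(ground_truth, cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  m <- ground_truth$gain_multiplier
  zg <- as.numeric(scale(log(m)))
  beta <- cfg$behavior_beta
  resid_sd <- sqrt(max(0, 1 - beta^2))
  rows <- list(); gen_mean <- list()
  for (ci in seq_along(cfg$behavior_base)) {
    cond <- names(cfg$behavior_base)[ci]
    eps <- with_seed(child_seed(cfg$seed, 5L, ci),
                     stats::rnorm(cfg$n_participants))
    pc_z <- beta * zg + resid_sd * eps
    mu <- cfg$behavior_base[ci] + cfg$behavior_scale * beta * zg
    pc <- clip(cfg$behavior_base[ci] + cfg$behavior_scale * pc_z, 0.25, 1)
    rows[[ci]] <- data.frame(participant = seq_len(cfg$n_participants),
                             condition = cond, pc = pc)
    gen_mean[[cond]] <- clip(mu, 0.25, 1)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "generative_mean") <- gen_mean
  out
}

#' Simulate a full synthetic cohort
#'
#' Feature streams, entrained pseudo-neural channels and behavioral scores,
#' with the planted ground truth stored alongside.
#'
#' @param cfg a [scenario_config()].
#' @param conditions conditions to generate (default c("A", "V")).
#' @return object of class `ct_cohort`.
#' @export
simulate_cohort <- function(cfg, conditions = c("A", "V")) {
  feats <- generate_feature_streams(cfg)
  nn <- generate_neural(feats, cfg, conditions = conditions)
  gt <- nn$ground_truth
  behavior <- generate_behavior(gt, cfg)
  gt$behavior_generative_mean <- attr(behavior, "generative_mean")
  structure(list(cfg = cfg, features = feats, neural = nn$neural,
                 channels = nn$channels, ground_truth = gt,
                 behavior = behavior),
            class = "ct_cohort")
}

#' @export
print.ct_cohort <- function(x, ...) {
  cat(sprintf("<ct_cohort> %d participants, %d trials (%.1f-%.1f s), %d channels, leak=%g, snr=%g, seed=%d\n",
              x$cfg$n_participants, x$cfg$n_trials,
              min(x$features$durations), max(x$features$durations),
              nrow(x$channels), x$cfg$leak, x$cfg$snr, x$cfg$seed))
  invisible(x)
}

.write_tsv <- function(df, path) {
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a cohort to a plain-text on-disk container
#'
#' Layout: `config.json` and `ground_truth.json` sidecars, `behavior.tsv`,
#' `features/trial_<k>.tsv`, and per participant/condition/trial neural TSVs
#' under `neural/`.  Values are written at full double precision so the
#' container round-trips losslessly via [read_cohort()].
#'
#' @param cohort a `ct_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ct_cohort"))
  dir.create(file.path(dir, "features"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "neural"), showWarnings = FALSE)
  cfg <- unclass(cohort$cfg)
  cfg$gains <- as.list(cfg$gains)            # keep names in JSON
  cfg$behavior_base <- as.list(cfg$behavior_base)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(cohort$ground_truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  .write_tsv(cohort$behavior, file.path(dir, "behavior.tsv"))
  for (k in seq_along(cohort$features$trials))
    .write_tsv(as.data.frame(cohort$features$trials[[k]]),
               file.path(dir, "features", sprintf("trial_%03d.tsv", k)))
  for (p in seq_along(cohort$neural))
    for (cond in names(cohort$neural[[p]]))
      for (k in seq_along(cohort$neural[[p]][[cond]]))
        .write_tsv(as.data.frame(cohort$neural[[p]][[cond]][[k]]),
                   file.path(dir, "neural", sprintf("p%02d_%s_trial_%03d.tsv", p, cond, k)))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir container directory.
#' @return a `ct_cohort`.
#' @export
read_cohort <- function(dir) {
  cfg_l <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  cfg_l$gains <- unlist(cfg_l$gains)
  cfg_l$behavior_base <- unlist(cfg_l$behavior_base)
  cfg <- do.call(scenario_config, cfg_l)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"), simplifyVector = TRUE)
  behavior <- utils::read.table(file.path(dir, "behavior.tsv"), header = TRUE, sep = "\t")
  feat_files <- sort(list.files(file.path(dir, "features"), full.names = TRUE))
  trials <- lapply(feat_files, function(f)
    as.matrix(utils::read.table(f, header = TRUE, sep = "\t")))
  durations <- vapply(trials, nrow, 0L) / cfg$feature_rate
  feats <- structure(list(trials = trials, durations = durations,
                          rate = cfg$feature_rate), class = "ct_features")
  nfile <- list.files(file.path(dir, "neural"))
  neural <- list()
  channels <- NULL
  for (f in sort(nfile)) {
    m <- regmatches(f, regexec("^p(\\d+)_([AV])_trial_(\\d+)\\.tsv$", f))[[1]]
    p <- as.integer(m[2]); cond <- m[3]; k <- as.integer(m[4])
    dat <- as.matrix(utils::read.table(file.path(dir, "neural", f), header = TRUE, sep = "\t"))
    if (is.null(channels))
      channels <- data.frame(channel = colnames(dat),
                             roi = sub("_\\d+$", "", colnames(dat)))
    if (length(neural) < p || is.null(neural[p][[1]])) neural[[p]] <- list()
    if (is.null(neural[[p]][[cond]])) neural[[p]][[cond]] <- list()
    neural[[p]][[cond]][[k]] <- dat
  }
  structure(list(cfg = cfg, features = feats, neural = neural,
                 channels = channels, ground_truth = gt, behavior = behavior),
            class = "ct_cohort")
}
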