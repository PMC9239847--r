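test_that("scenario configuration validates its inputs", {
  expect_error(scenario_config(coherence_target = 1.2), "coherence_target")
  expect_error(scenario_config(coherence_target = -0.1), "coherence_target")
  expect_error(scenario_config(feature_rate = 0), "feature_rate")
  expect_error(scenario_config(gains = c(aud_env = 1)), "gains missing")
})

test_that("generation is bit-identical under the same seed and diverges across seeds", {
  cfg <- scenario_config(n_participants = 2, n_trials = 4, seed = 5)
  a <- simulate_cohort(cfg); b <- simulate_cohort(cfg)
  expect_identical(a$features$trials, b$features$trials)
  expect_identical(a$neural, b$neural)
  expect_identical(a$behavior, b$behavior)
  c2 <- simulate_cohort(scenario_config(n_participants = 2, n_trials = 4, seed = 6))
  expect_false(identical(a$features$trials[[1]], c2$features$trials[[1]]))
})

test_that("trial durations respect the truncation range and slopes are exact differences", {
  cfg <- scenario_config(n_trials = 60, seed = 2)
  fs <- generate_feature_streams(cfg)
  expect_true(all(fs$durations >= 4.6 & fs$durations <= 6.5))
  m <- fs$trials[[1]]
  expect_equal(m[, "aud_slope"], c(0, diff(m[, "aud_env"])), ignore_attr = TRUE)
  expect_equal(m[, "lip_slope"], c(0, diff(m[, "lip_area"])), ignore_attr = TRUE)
  expect_true(all(m[, c("aud_env", "aud_pitch", "lip_area", "lip_width")] >= 0))
})

test_that("feature spectra decay with frequency over 1-8 Hz", {
  cfg <- scenario_config(n_trials = 40, seed = 3)
  fs <- generate_feature_streams(cfg)
  sc <- feature_spectra_and_coherence(fs$trials)
  sel <- sc$freq >= 1 & sc$freq <= 8
  for (f in c("aud_env", "lip_area", "aud_pitch")) {
    expect_lt(cor(sc$freq[sel], sc$log_psd[f, sel], method = "spearman"), -0.9)
  }
})

test_that("zero coherence target yields independent envelope and lip streams", {
  cfg <- scenario_config(n_trials = 60, coherence_target = 0, seed = 4)
  sc <- feature_spectra_and_coherence(generate_feature_streams(cfg)$trials)
  expect_true(all(sc$band_coherence$coherence <= 0.05))
})

test_that("noise-free channels recover the planted lag by cross-correlation", {
  # cross-correlation oracle on the drive itself, independent of the MI path
  cfg <- scenario_config(n_participants = 1, n_trials = 2, tracking_lag = 0.1,
                         snr = 1e6, gain_multiplier_sd = 0,
                         gains = setNames(c(0, 0, 1, 0, 0, 0), feature_names()),
                         seed = 6)
  coh <- simulate_cohort(cfg, conditions = "A")
  tr <- coh$features$trials[[1]]
  ch <- coh$neural[[1]][["A"]][[1]][, "temporal_1"]
  pitch <- (tr[, "aud_pitch"] - mean(tr[, "aud_pitch"])) / sd(tr[, "aud_pitch"])
  cc <- ccf(ch, pitch, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 5)  # 100 ms at 50 Hz
})

test_that("lags beyond the trial duration are rejected", {
  cfg <- scenario_config(n_participants = 1, n_trials = 2, seed = 1)
  cfg$tracking_lag <- c(10, 10)  # 10 s against ~5 s trials
  fs <- generate_feature_streams(cfg)
  expect_error(generate_neural(fs, cfg), "lag exceeds")
})

test_that("behavioral scores stay in [0.25, 1] and decouple when beta = 0", {
  for (s in 1:20) {
    cfg <- scenario_config(n_participants = 18, behavior_beta = 0.9, seed = s)
    gt <- list(gain_multiplier = withr::with_seed(s, exp(rnorm(18, 0, 0.3))))
    bh <- generate_behavior(gt, cfg)
    expect_true(all(bh$pc >= 0.25 & bh$pc <= 1))
  }
  # beta = 0: regression on the planted gain recovers ~0
  betas <- sapply(1:100, function(s) {
    cfg <- scenario_config(n_participants = 18, behavior_beta = 0, seed = s)
    gm <- withr::with_seed(1000 + s, exp(rnorm(18, 0, 0.3)))
    bh <- generate_behavior(list(gain_multiplier = gm), cfg)
    df <- data.frame(pc = bh$pc[bh$condition == "V"], gain = log(gm))
    partial_regression(df, "pc", "gain")$coefficients$beta[2]
  })
  expect_lt(abs(mean(betas)), 0.05)
})

test_that("the on-disk container round-trips a cohort losslessly", {
  dir <- withr::local_tempdir()
  cfg <- scenario_config(n_participants = 2, n_trials = 3, n_channels = 1, seed = 9)
  coh <- simulate_cohort(cfg)
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$cfg$seed, cfg$seed)
  expect_equal(back$cfg$gains, cfg$gains)
  for (k in seq_along(coh$features$trials))
    expect_equal(unname(back$features$trials[[k]]), unname(coh$features$trials[[k]]),
                 tolerance = 1e-14)
  expect_equal(back$neural[[2]][["V"]][[3]], coh$neural[[2]][["V"]][[3]],
               tolerance = 1e-14, ignore_attr = TRUE)
  expect_equal(back$behavior$pc, coh$behavior$pc, tolerance = 1e-14)
  expect_equal(unlist(back$ground_truth$lags), unname(coh$ground_truth$lags),
               tolerance = 1e-12)
})
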