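test_that("random time shifts are invertible, joint, and cover their range uniformly", {
  x <- withr::with_seed(1, matrix(rnorm(600), ncol = 2))
  s <- random_time_shift(x, rate = 50, t_min = 2, seed = 3)
  back <- copulatrack:::circ_shift(s, -attr(s, "shift"))
  expect_identical(unname(back), unname(x))

  # joint shift preserves the cross-correlation between columns
  cc0 <- ccf(x[, 1], x[, 2], lag.max = 5, plot = FALSE)$acf
  cc1 <- ccf(s[, 1], s[, 2], lag.max = 5, plot = FALSE)$acf
  expect_equal(cc1, cc0, tolerance = 0.15)

  n <- 4000
  shifts <- withr::with_seed(5, copulatrack:::.draw_shifts(1000, n, 50, 2))
  expect_true(all(shifts >= 100 & shifts <= n - 100))
  jit <- withr::with_seed(6, shifts - 100 + runif(1000))
  expect_gt(suppressWarnings(ks.test(jit / (n - 200 + 1), "punif")$p.value), 0.01)

  expect_error(random_time_shift(matrix(0, 100, 1), rate = 50, t_min = 2),
               "too short")
})

test_that("bias-matched MI matches plain MI under dependence and has matched bias under independence", {
  # strong latent dependence: shifting destroys the conditioner's relevance
  p <- rho_pair(10000, 0.9, seed = 7)
  bm <- bias_matched_mi(p$x, p$y, reps = 20, seed = 1)
  expect_lt(abs(bm$value - gcmi(p$x, p$y)$value), 0.03)

  # independent data: matches a CMI with an independent conditioner on average
  diffs <- sapply(1:60, function(s) {
    withr::with_seed(100 + s, {
      x <- copulatrack:::.shaped_noise(1500, 2)
      y <- copulatrack:::.shaped_noise(1500, 2)
      z <- copulatrack:::.shaped_noise(1500, 2)
      bias_matched_mi(x, y, reps = 8, seed = s)$value -
        gcmi_conditional(x, y, z)$value
    })
  })
  expect_lt(abs(mean(diffs)), 0.005)

  # averaging more shifts reduces the estimator's variance
  x0 <- withr::with_seed(9, copulatrack:::.shaped_noise(800, 1))
  y0 <- withr::with_seed(10, copulatrack:::.shaped_noise(800, 1))
  v1 <- sapply(1:40, function(s) bias_matched_mi(x0, y0, reps = 1, seed = s)$value)
  v50 <- sapply(1:40, function(s) bias_matched_mi(x0, y0, reps = 30, seed = 500 + s)$value)
  expect_lt(var.test(v50, v1, alternative = "less")$p.value, 0.05)
})

test_that("baseline subtraction centers null data at zero and is seed-deterministic", {
  x <- withr::with_seed(11, copulatrack:::.shaped_noise(5000, 1))
  y <- withr::with_seed(12, copulatrack:::.shaped_noise(5000, 1))
  est <- null_baseline_subtract(function(a, b) gcmi(a, b), x, y, reps = 40, seed = 2)
  expect_true(est$baseline_subtracted)
  expect_lt(abs(est$value), 0.01)

  est2 <- null_baseline_subtract(function(a, b) gcmi(a, b), x, y, reps = 40, seed = 2)
  expect_identical(est$value, est2$value)
})

test_that("lag profiles localize a planted delay and validate their inputs", {
  dp <- delayed_pair(n = 8000, delay = 5, noise = 0.3)
  lp <- lag_profile(dp$x, dp$y)
  expect_s3_class(lp, "lag_profile")
  expect_equal(lp$lag_s, seq(0, 0.5, by = 0.02))
  expect_equal(lp$lag_s[which.max(lp$mi)], 0.10)
  expect_gt(lp$mi[lp$lag_s == 0.10], lp$mi[lp$lag_s == 0.30])

  expect_error(lag_profile(matrix(rnorm(40), ncol = 1), rnorm(40)), "too short")
})

test_that("group-level optimal lag aggregates as median over participants, summed conditions", {
  grid <- seq(0, 0.5, by = 0.02)
  mk <- function(p, cond, peak) data.frame(participant = p, condition = cond,
                                           lag_s = grid,
                                           mi = dnorm(grid, peak, 0.08))
  same <- do.call(rbind, lapply(1:5, mk, cond = "A", peak = 0.10))
  expect_equal(optimal_lag_group(same), 0.10)

  split <- rbind(do.call(rbind, lapply(1:3, mk, cond = "A", peak = 0.08)),
                 do.call(rbind, lapply(4:6, mk, cond = "A", peak = 0.12)))
  expect_equal(optimal_lag_group(split), 0.10)

  single <- mk(1, "A", 0.22)
  expect_equal(optimal_lag_group(single), 0.22)

  # exact tie broken toward the smaller lag
  flat <- data.frame(participant = 1, condition = "A", lag_s = grid,
                     mi = rep(1, length(grid)))
  expect_equal(optimal_lag_group(flat), 0)
})

test_that("windowed MI averages the profile around the lag and clips at grid edges", {
  dp <- delayed_pair(n = 6000, delay = 5, noise = 0.5)
  lp <- lag_profile(dp$x, dp$y)
  wm <- windowed_mi(dp$x, dp$y, optimal_lag = 0.10)
  expect_equal(wm$metadata$n_lags, 7)
  expect_equal(wm$value, mean(lp$mi[abs(lp$lag_s - 0.10) <= 0.0601]),
               tolerance = 1e-10)
  # averaging a peaked profile dilutes the peak
  expect_lt(wm$value, max(lp$mi))

  edge <- windowed_mi(dp$x, dp$y, optimal_lag = 0)
  expect_equal(edge$metadata$n_lags, 4)
})

test_that("shift-folded covariance paths agree with direct estimation on shifted data", {
  x <- withr::with_seed(13, copulatrack:::.shaped_noise(3000, 3))
  y <- withr::with_seed(14, x[, 1] + 0.7 * copulatrack:::.shaped_noise(3000, 1)[, 1])
  Xn <- copula_normalize(x); Yn <- copula_normalize(y)
  Sxx <- copulatrack:::.ncov(Xn); Syy <- copulatrack:::.ncov(Yn)
  for (e in c(0, 7, 150)) {
    fast <- copulatrack:::.mi_at(Xn, Yn, Sxx, Syy, e)
    direct <- gcmi(x, copulatrack:::circ_shift(y, -e))$value
    expect_equal(fast, direct, tolerance = 1e-9)
  }
  z <- withr::with_seed(15, copulatrack:::.shaped_noise(3000, 2))
  Zn <- copula_normalize(z)
  Szz <- copulatrack:::.ncov(Zn); Sxz <- copulatrack:::.ncov(Xn, Zn)
  fastc <- copulatrack:::.cmi_at(Xn, Zn, Yn, Sxx, Szz, Sxz, Syy, 9)
  directc <- gcmi_conditional(x, copulatrack:::circ_shift(y, -9), z)$value
  expect_equal(fastc, directc, tolerance = 1e-9)
})

test_that("track_cohort produces a complete, reproducible estimate table", {
  coh <- small_cohort()
  reps <- list(bias_match = 6, baseline = 5, max_null = 8)
  tr <- track_cohort(coh, reps = reps, seed = 11)
  mt <- tr$mi_table
  expect_equal(sort(unique(mt$kind)), c("cmi", "mi", "mi_bias_matched"))
  expect_equal(nrow(mt), 3 * 2 * 2 * 2 * 3)  # participants x cond x roi x sets(2 groups) x kinds
  expect_true(all(is.finite(mt$value_bits)))
  expect_true(all(table(tr$surrogates$feature_set) > 0))
  # driven cell outranks an undriven one
  a_temp <- median(mt$value_bits[mt$condition == "A" & mt$roi == "temporal" &
                                   mt$feature_set == "AudFeat" & mt$kind == "mi"])
  a_occ <- median(mt$value_bits[mt$condition == "A" & mt$roi == "occipital" &
                                  mt$feature_set == "AudFeat" & mt$kind == "mi"])
  expect_gt(a_temp, 10 * a_occ)

  tr2 <- track_cohort(coh, reps = reps, seed = 11)
  expect_identical(tr$mi_table$value_bits, tr2$mi_table$value_bits)
})

test_that("downstream MI grows monotonically with the planted gain at fixed noise", {
  # channel noise has unit variance up to the snr normalization, so raising
  # the planted gain at fixed noise is equivalent to snr = gain^2
  levels <- c(0.2, 0.5, 1, 2, 4)
  med <- sapply(seq_along(levels), function(i) {
    cfg <- scenario_config(n_participants = 2, n_trials = 8, snr = levels[i]^2,
                           tracking_lag = 0.1, seed = 17)
    coh <- simulate_cohort(cfg, conditions = "A")
    st <- copulatrack:::.lean_group_stat(coh, canonical_bands()[["1-3"]], "A",
                                         "temporal", feature_groups()$AudFeat,
                                         reps_surr = 2, seed = 1)
    median(st$observed)
  })
  expect_gt(cor(seq_along(levels), med, method = "spearman"), 0.9)
})
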