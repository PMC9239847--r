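test_that("z-scoring across participants is exact", {
  expect_equal(zscore_across_participants(c(1, 2, 3)), c(-1, 0, 1))
  x <- withr::with_seed(1, rnorm(18, 5, 3))
  z <- zscore_across_participants(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
  expect_error(zscore_across_participants(rep(2, 10)), "zero variance")
  expect_error(zscore_across_participants(c(1, 2)), "3 participants")
})

test_that("per-band z-scoring then averaging gives one confound per participant", {
  m <- withr::with_seed(2, matrix(rnorm(18 * 3, sd = c(1, 10, 100)), 18, 3))
  avg <- zscore_bands_average(m)
  expect_length(avg, 18)
  expect_lt(abs(mean(avg)), 1e-12)
})

test_that("partial regression recovers planted couplings and calibrates its p-values", {
  # perfect single predictor
  df <- data.frame(y = c(1, 3, 2, 5, 4, 6), x = c(1, 3, 2, 5, 4, 6))
  fit <- suppressWarnings(partial_regression(df, "y", "x"))
  expect_equal(fit$coefficients$beta[fit$coefficients$term == "x"], 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # standardized-beta recovery with a confound in the model
  est <- withr::with_seed(3, replicate(300, {
    x <- rnorm(18); conf <- rnorm(18)
    y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(18)
    f <- partial_regression(data.frame(y = y, x = x, conf = conf), "y", "x", "conf")
    f$coefficients$beta[f$coefficients$term == "x"]
  }))
  expect_lt(abs(mean(est) - 0.6), 0.05)

  # orthogonal target: type-I rate of the t-test at alpha = .05
  p0 <- withr::with_seed(4, replicate(800, {
    x <- rnorm(18); y <- rnorm(18)
    f <- partial_regression(data.frame(y = y, x = x), "y", "x")
    f$coefficients$p[f$coefficients$term == "x"]
  }))
  expect_gt(mean(p0 < 0.05), 0.03)
  expect_lt(mean(p0 < 0.05), 0.07)

  expect_error(partial_regression(data.frame(y = rnorm(4), x = rnorm(4),
                                             a = rnorm(4), b = rnorm(4)),
                                  "y", c("x", "a", "b")),
               "n_participants")
  xx <- withr::with_seed(5, rnorm(12))
  expect_error(partial_regression(data.frame(y = rnorm(12), x = xx, x2 = 2 * xx),
                                  "y", c("x", "x2")),
               "collinear")
})

test_that("BIC Bayes factors follow the exp(dBIC/2) form and penalize noise predictors", {
  df <- withr::with_seed(6, data.frame(y = rnorm(18), x = rnorm(18)))
  full <- lm(y ~ x, df); red <- lm(y ~ 1, df)
  expect_equal(bayes_factor_bic(full, full), 1)
  expect_equal(bayes_factor_bic(full, red),
               exp((BIC(red) - BIC(full)) / 2), tolerance = 1e-12)
  expect_error(bayes_factor_bic(lm(y ~ 1, df), lm(y ~ x, df)), "not nested")

  bf <- withr::with_seed(7, replicate(200, {
    d <- data.frame(y = rnorm(18), noise = rnorm(18))
    bayes_factor_bic(lm(y ~ noise, d), lm(y ~ 1, d))
  }))
  expect_gt(mean(bf < 1), 0.5)
})

test_that("a known BIC difference maps to BF = 10", {
  df <- data.frame(y = rnorm(10), x = rnorm(10))
  f1 <- lm(y ~ x, df); f2 <- lm(y ~ 1, df)
  # algebra of the formula: dBIC = 2 ln 10 <=> BF = 10
  expect_equal(exp((2 * log(10)) / 2), 10)
})

test_that("partial residuals satisfy the slope identity", {
  df <- withr::with_seed(8, data.frame(y = rnorm(18), x1 = rnorm(18), x2 = rnorm(18)))
  df$y <- 0.5 * df$x1 - 0.3 * df$x2 + df$y
  fit <- partial_regression(df, "y", c("x1", "x2"))
  for (tgt in c("x1", "x2")) {
    pr <- partial_residuals(fit, tgt)
    slope <- coef(lm(partial_residual ~ x, pr))[["x"]]
    beta <- fit$coefficients$beta[fit$coefficients$term == tgt]
    expect_equal(slope, beta, tolerance = 1e-10)
  }
  # zero-beta target: partial residuals equal the full-model residuals
  fit0 <- lm(y ~ x1 + x2, transform(df, y = df$x1))
  pr0 <- partial_residuals(fit0, "x2")
  expect_equal(pr0$partial_residual, unname(residuals(fit0) + coef(fit0)[["x2"]] * df$x2),
               tolerance = 1e-12)
  expect_error(partial_residuals(fit, "zzz"), "not a model predictor")
})

test_that("orthogonal predictors make partial residuals match simple-regression residuals plus beta x", {
  n <- 64
  x1 <- rep(c(-1, 1), each = n / 2)
  x2 <- rep(c(-1, 1), times = n / 2)  # exactly orthogonal to x1
  y <- withr::with_seed(9, 0.8 * x1 + 0.2 * x2 + rnorm(n))
  fit <- lm(y ~ x1 + x2)
  pr <- partial_residuals(fit, "x1")
  simple <- residuals(lm(y ~ x2))
  expect_equal(pr$partial_residual, unname(simple), tolerance = 1e-10)
})

test_that("the model flags the planted behavioral target and not the control", {
  flags <- withr::with_seed(10, sapply(1:60, function(r) {
    cfg <- scenario_config(n_participants = 18, behavior_beta = 0.8,
                           seed = 5000 + r)
    gm <- exp(rnorm(18, 0, 0.3))
    bh <- generate_behavior(list(gain_multiplier = gm), cfg)
    df <- data.frame(pc = bh$pc[bh$condition == "V"],
                     target = log(gm), control = rnorm(18))
    f <- partial_regression(df, "pc", c("target", "control"))
    cf <- f$coefficients
    c(target = cf$p[cf$term == "target"] < 0.05,
      control = cf$p[cf$term == "control"] < 0.05)
  }))
  expect_gt(mean(flags["target", ]), 0.9)
  expect_lt(mean(flags["control", ]), 0.2)
})
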