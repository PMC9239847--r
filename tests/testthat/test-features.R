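test_that("broadband envelope tracks amplitude modulation and handles edge cases", {
  fs <- 22050
  t <- seq(0, 4, by = 1 / fs)
  # 1 kHz carrier, 100% AM at 2 Hz -> envelope spectrum peaks at 2 Hz
  am <- (1 + sin(2 * pi * 2 * t)) * sin(2 * pi * 1000 * t)
  env <- compute_broadband_envelope(am, fs)
  ws <- welch_spectra(env - mean(env), rate = 50, win_sec = 1)
  fpos <- ws$freq[ws$freq > 0]
  pk <- fpos[which.max(ws$sxx[ws$freq > 0])]
  expect_equal(pk, 2)

  # pure tone: near-constant envelope away from edges
  tone <- sin(2 * pi * 1000 * t)
  envt <- compute_broadband_envelope(tone, fs)
  core <- seq(20, length(envt) - 20)
  expect_lt(sd(envt[core]) / mean(envt[core]), 0.05)

  # polarity invariance and nonnegativity
  expect_equal(compute_broadband_envelope(-tone, fs), envt, tolerance = 1e-9)
  expect_true(all(envt >= 0))

  # silence
  expect_lt(max(compute_broadband_envelope(numeric(fs), fs)), 1e-10)

  expect_error(compute_broadband_envelope(tone, fs = 16000), "20 kHz")
})

test_that("slope is the first difference with a leading zero and is linear", {
  expect_equal(compute_slope(rep(3, 10)), rep(0, 10), ignore_attr = TRUE)
  expect_equal(compute_slope(seq(0, 9, by = 1) * 0.4), c(0, rep(0.4, 9)), ignore_attr = TRUE)

  fs <- 50
  t <- seq(0, 4, by = 1 / fs)
  x <- sin(2 * pi * 1 * t)
  s <- compute_slope(x)
  w <- 2 * pi * 1
  closed <- 2 * sin(w / (2 * fs)) * cos(w * (t - 1 / (2 * fs)))
  expect_lt(max(abs(s[-1] - closed[-1])), 1e-12)

  y <- withr::with_seed(1, rnorm(100))
  expect_equal(compute_slope(5 * y), 5 * compute_slope(y), ignore_attr = TRUE)
})

test_that("pitch stand-in recovers known fundamentals", {
  fs <- 22050
  t <- seq(0, 2, by = 1 / fs)
  saw <- 2 * ((120 * t) %% 1) - 1
  p <- estimate_pitch(saw, fs)
  expect_lt(abs(median(p$samples[p$voiced]) - 120), 2)

  expect_warning(ps <- estimate_pitch(numeric(fs), fs), "no voiced")
  expect_true(all(!ps$voiced))
  expect_true(all(is.na(ps$samples)))

  # linear glide 100 -> 200 Hz over 2 s
  f_inst <- 100 + 50 * t
  glide <- sin(2 * pi * (100 * t + 25 * t^2))
  pg <- estimate_pitch(glide, fs)
  idx <- which(pg$voiced)
  idx <- idx[idx > 5 & idx < length(pg$voiced) - 5]
  truth <- 100 + 50 * (idx - 1) / 50
  expect_lt(max(abs(pg$samples[idx] - truth)), 5)
})

test_that("lip features interpolate linearly from 25 to 50 fps", {
  n <- 50
  tt <- (0:(n - 1)) / 25
  tab <- data.frame(time = tt, lip_area = rep(7, n), lip_width = rep(2, n))
  lf <- extract_lip_features(tab)
  expect_equal(length(lf$lip_area), 2 * n - 1)
  expect_equal(unique(round(lf$lip_area, 12)), 7)

  # triangular wave: interpolated points lie exactly on the piecewise-linear path
  tri <- abs(((0:(n - 1)) %% 8) - 4)
  tab$lip_area <- tri
  lf2 <- extract_lip_features(tab)
  t50 <- seq(tt[1], tt[n], by = 1 / 50)
  oracle <- approx(tt, tri, xout = t50)$y
  expect_equal(lf2$lip_area, oracle, tolerance = 1e-12, ignore_attr = TRUE)

  # slope computed at native rate then interpolated
  expect_equal(lf2$lip_slope[1], 0, ignore_attr = TRUE)

  expect_error(extract_lip_features(data.frame(time = c(0, 0.04, 0.3),
                                               lip_area = 1:3, lip_width = 1:3)),
               "gap")
  expect_error(extract_lip_features(data.frame(time = c(0, 0.08, 0.04),
                                               lip_area = 1:3, lip_width = 1:3)),
               "increasing")
})

test_that("Welch coherence behaves at its closed-form anchor points", {
  n <- 180 * 250
  x <- withr::with_seed(3, rnorm(n))
  noise <- withr::with_seed(4, rnorm(n))

  self <- welch_spectra(x, x, rate = 50)
  expect_true(all(self$coherence > 1 - 1e-9))

  indep <- welch_spectra(x, noise, rate = 50)
  expect_lt(mean(indep$coherence), 0.05)
  expect_true(all(indep$coherence >= 0 & indep$coherence <= 1))

  # y = x + independent noise at unit variance ratio -> coherence 0.5
  half <- welch_spectra(x, x + noise, rate = 50)
  expect_lt(max(abs(half$coherence[2:24] - 0.5)), 0.05)
})

test_that("cohort-level spectra and coherence pool across trials and skip short ones", {
  trials <- withr::with_seed(5, lapply(1:30, function(i) {
    m <- matrix(rnorm(250 * 2), 250, 2); colnames(m) <- c("a", "b"); m
  }))
  res <- feature_spectra_and_coherence(trials, pairs = list(c("a", "b")))
  expect_lt(res$band_coherence$coherence[2], 0.05)
  expect_equal(dim(res$log_psd), c(2L, 26L))

  short <- c(trials, list({m <- matrix(rnorm(40 * 2), 40, 2); colnames(m) <- c("a", "b"); m}))
  expect_warning(feature_spectra_and_coherence(short, pairs = list(c("a", "b"))),
                 "skipped 1")
})

test_that("WAV files round-trip through the PCM16 reader/writer", {
  path <- withr::local_tempfile(fileext = ".wav")
  x <- sin(2 * pi * 440 * seq(0, 0.5, by = 1 / 8000)) * 0.8
  write_wav(x, 8000, path)
  back <- read_wav(path)
  expect_equal(back$rate, 8000)
  expect_equal(back$samples, x, tolerance = 1e-4)
})
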