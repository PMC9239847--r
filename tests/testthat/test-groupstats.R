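test_that("max null distribution keeps the top values and thresholds at the 99th percentile", {
  const <- build_max_null(rep(3.2, 2500))
  expect_equal(const$threshold, 3.2)

  pool <- withr::with_seed(1, rnorm(50000))
  mn <- build_max_null(pool)
  brute <- quantile(sort(pool, decreasing = TRUE)[1:2000], 0.99)
  expect_equal(mn$threshold, unname(brute))
  expect_equal(length(mn$values), 2000L)

  expect_warning(small <- build_max_null(rnorm(500)), "using all")
  expect_equal(length(small$values), 500L)
  expect_error(build_max_null(numeric(0)), "no surrogate")
})

test_that("max-correction threshold is monotone nondecreasing in the correction scope", {
  vals <- withr::with_seed(2, rnorm(30000))
  thr <- sapply(c(5000, 10000, 20000, 30000), function(k)
    build_max_null(vals[seq_len(k)], n_keep = min(2000, k))$threshold)
  expect_true(all(diff(thr) >= -1e-12))
})

test_that("the group-median test uses a strict threshold", {
  null <- build_max_null(seq(0, 1, length.out = 3000))
  below <- test_group_median(rep(null$threshold - 0.1, 5), null)
  at <- test_group_median(rep(null$threshold, 5), null)
  above <- test_group_median(rep(null$threshold + 0.1, 5), null)
  expect_false(below$significant)
  expect_false(at$significant)   # boundary: strict inequality
  expect_true(above$significant)
  expect_error(test_group_median(c(1, 2), null), "3 participants")
})

test_that("the Wilcoxon z statistic matches the textbook formula on toy tables", {
  # hand-computed: d = (2, -1, 3, 5), |d| ranks (2, 1, 3, 4), W+ = 9
  a <- c(3, 1, 7, 9); b <- c(1, 2, 4, 4)
  nz <- 4; w <- 9; mu <- nz * (nz + 1) / 4; sig <- sqrt(nz * (nz + 1) * (2 * nz + 1) / 24)
  expect_equal(wilcoxon_signed_z(a, b), (w - mu - 0.5) / sig)
  expect_equal(wilcoxon_signed_z(a, b, continuity = FALSE), (w - mu) / sig)

  # zeros dropped; all-zero differences give z = 0
  expect_equal(wilcoxon_signed_z(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(wilcoxon_signed_z(c(1, 2, 3, 9), c(1, 2, 3, 4)),
               wilcoxon_signed_z(9, 4))

  # tie-corrected variance, length 6 with tied |d|
  a2 <- c(2, 2, 5, 5, 1, 7); b2 <- c(1, 1, 3, 3, 4, 2)
  d <- a2 - b2; r <- rank(abs(d)); w2 <- sum(r[d > 0])
  ties <- table(r)
  sig2 <- 6 * 7 * 13 / 24 - sum(ties^3 - ties) / 48
  expect_equal(wilcoxon_signed_z(a2, b2),
               (w2 - 10.5 - 0.5 * sign(w2 - 10.5)) / sqrt(sig2))
})

test_that("permutation Wilcoxon flags large shifts and stays silent under equality", {
  same <- matrix(rnorm(36), 18, 2)
  res0 <- permutation_wilcoxon_paired(same, same, n_perm = 300, seed = 1)
  expect_equal(res0$statistic, c(0, 0))
  expect_false(any(res0$significant))

  a <- withr::with_seed(3, matrix(rnorm(18), ncol = 1))
  res1 <- permutation_wilcoxon_paired(a + 10, a, n_perm = 2000, alpha = 0.01, seed = 2)
  expect_true(res1$significant)
  expect_true(all(res1$p > 0))
  expect_true(all(res1$p >= 1 / 2001))
})

test_that("permutation Wilcoxon max-correction controls the FWER under exchangeable nulls", {
  hits <- withr::with_seed(4, sapply(1:200, function(r) {
    a <- matrix(rnorm(12 * 6), 12, 6)
    b <- matrix(rnorm(12 * 6), 12, 6)
    any(permutation_wilcoxon_paired(a, b, n_perm = 250, alpha = 0.01)$significant)
  }))
  fwer <- mean(hits)
  expect_lte(fwer, 0.01 + 2 * sqrt(0.01 * 0.99 / 200) + 1e-12)
})

test_that("Kruskal-Wallis chi-square matches a brute-force rank computation", {
  vals <- c(1.2, 3.4, 2.2, 5.1, 4.4, 0.7, 2.9, 3.3, 6.0, 1.1, 2.5, 4.8, 3.9, 0.3, 5.5)
  grp <- rep(c("a", "b", "c"), each = 5)
  res <- kruskal_wallis_posthoc(vals, grp, alpha = 0.05)
  # textbook: H = 12/(N(N+1)) * sum n_i Rbar_i^2 - 3(N+1), no ties here
  r <- rank(vals); N <- 15
  H <- 12 / (N * (N + 1)) * sum(tapply(r, grp, function(v) length(v) * mean(v)^2)) - 3 * (N + 1)
  expect_equal(res$statistic, H, tolerance = 1e-12)
  expect_equal(res$epsilon_sq, H / (N - 1), tolerance = 1e-12)
  expect_equal(res$df, 2)

  ident <- kruskal_wallis_posthoc(rep(c(1, 2, 3, 4, 5, 6), 3) + rep(0:2, each = 6) * 0,
                                  rep(c("a", "b", "c"), each = 6))
  expect_gt(ident$p, 0.9)

  expect_error(kruskal_wallis_posthoc(rnorm(10), rep(c("a", "b"), 5)), "3 groups")
  expect_error(kruskal_wallis_posthoc(rnorm(5), c("a", "a", "b", "b", "c")), ">= 2")
})

test_that("Tukey-Kramer post hoc flags only the separated group", {
  x <- withr::with_seed(5, c(rnorm(18), rnorm(18), rnorm(18) + 6))
  g <- rep(c("g1", "g2", "g3"), each = 18)
  res <- kruskal_wallis_posthoc(x, g, alpha = 0.01)
  expect_true(res$significant)
  ph <- res$posthoc
  sep <- ph$group1 == "g3" | ph$group2 == "g3"
  expect_true(all(ph$significant[sep]))
  expect_false(any(ph$significant[!sep]))
})

test_that("BH step-up decisions match the brute-force definition", {
  res <- bh_fdr(c(0.001, 0.008, 0.039, 0.041), q = 0.01)
  expect_equal(res$significant, c(TRUE, FALSE, FALSE, FALSE))

  expect_false(any(bh_fdr(rep(1, 6))$significant))
  expect_true(bh_fdr(0.005, q = 0.01)$significant)
  expect_equal(nrow(bh_fdr(numeric(0))), 0L)
  expect_error(bh_fdr(c(0.1, 1.4)), "outside")

  brute_bh <- function(p, q) {
    m <- length(p); o <- order(p)
    k <- max(c(0, which(p[o] <= (1:m) * q / m)))
    rej <- rep(FALSE, m)
    if (k > 0) rej[o[1:k]] <- TRUE
    rej
  }
  withr::with_seed(6, {
    for (i in 1:40) {
      m <- sample(1:8, 1)
      p <- round(runif(m), 3)
      q <- sample(c(0.01, 0.05, 0.1), 1)
      expect_equal(bh_fdr(p, q)$significant, brute_bh(p, q))
    }
  })
})
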