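test_that("a pool of identical trials always emits that trial's waveform", {
  n_t <- 30
  wave <- sin(seq(0, 4 * pi, length.out = n_t))
  data <- array(0, c(6, 2, n_t))
  for (i in 1:6) for (c in 1:2) data[i, c, ] <- wave * c
  ts <- trial_set(data, rt_ms = rep(300, 6), subject_id = rep("S01", 6),
                  sfreq = 100, channels = c("A", "B"))
  labels <- factor(rep("fast", 6), levels = c("fast", "medium", "slow", "outlier"))
  aug <- suppressWarnings(
    bootstrap_erps(ts, labels, bootstrap_params(r = 3, n = 5, n_alpha = 2, seed = 1)))
  for (i in seq_len(dim(aug$erps)[1])) {
    expect_equal(aug$erps[i, 1, ], wave, tolerance = 1e-12)
    expect_equal(aug$erps[i, 2, ], 2 * wave, tolerance = 1e-12)
  }
})

test_that("emitted sample counts match the discrete-event drop-schedule oracle", {
  # the study-scale case: pool 100, r 50, alpha 0.2, drop every 10 of 1500
  p <- bootstrap_params(r = 50, alpha = c(fast = 0.3, medium = 0.2, slow = 0.1),
                        n = 1500, n_alpha = 10)
  expect_equal(expected_sample_count(100, p, "medium"),
               simulate_drop_schedule(100, 50, 0.2, 1500, 10))
  # full 200-case grid across pool sizes, rates, and caps
  grid <- expand.grid(pool = c(0, 3, 10, 25, 40, 50, 51, 60, 75, 120),
                      r = c(5, 12, 25, 50),
                      alpha = c(0.1, 0.25, 0.45, 0.8),
                      stringsAsFactors = FALSE)
  grid$n <- rep(c(30, 200), length.out = nrow(grid))
  grid$n_alpha <- rep(c(3, 7, 10), length.out = nrow(grid))
  expect_gte(nrow(grid), 160)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    prm <- bootstrap_params(r = g$r, alpha = c(fast = g$alpha, medium = 0.2, slow = 0.1),
                            n = g$n, n_alpha = g$n_alpha)
    expect_equal(expected_sample_count(g$pool, prm, "fast"),
                 simulate_drop_schedule(g$pool, g$r, g$alpha, g$n, g$n_alpha),
                 label = sprintf("grid case %d", i))
  }
})

test_that("closed-form counts hit the piecewise boundary cases", {
  p <- bootstrap_params(r = 50, n = 1500, n_alpha = 10)
  expect_equal(expected_sample_count(10, p, "fast"), 1L)  # pool below r
  expect_equal(expected_sample_count(0, p, "fast"), 0L)   # empty pool
  # drop schedule slower than the iteration cap: count saturates at n
  expect_equal(expected_sample_count(1e6, p, "slow"), 1500L)
})

test_that("bootstrap output size equals the closed form per pool, and conserves trials", {
  ts <- tiny_trial_set(80, n_ch = 2, n_t = 20, seed = 6)
  labels <- factor(rep(c("fast", "medium"), each = 40), levels = c("fast", "medium", "slow", "outlier"))
  prm <- bootstrap_params(r = 10, n = 60, n_alpha = 5, seed = 3)
  aug <- suppressWarnings(bootstrap_erps(ts, labels, prm))
  for (cat in c("fast", "medium")) {
    expect_equal(sum(aug$category == cat),
                 expected_sample_count(40, prm, cat))
  }
  expect_true(all(aug$provenance <= prm$r))
})

test_that("augmentation is deterministic under seed and excludes outliers", {
  ts <- tiny_trial_set(30, seed = 2)
  labels <- factor(c(rep("fast", 12), rep("slow", 12), rep("outlier", 6)),
                   levels = c("fast", "medium", "slow", "outlier"))
  prm <- bootstrap_params(r = 4, n = 10, n_alpha = 3, seed = 9)
  a1 <- suppressWarnings(suppressMessages(bootstrap_erps(ts, labels, prm)))
  a2 <- suppressWarnings(suppressMessages(bootstrap_erps(ts, labels, prm)))
  expect_identical(a1$erps, a2$erps)
  expect_true(all(a1$category %in% c("fast", "slow")))
})

test_that("augmentation raises the minority-category share", {
  # imbalanced pools, study-style dropout rates: the slow share must rise
  ts <- tiny_trial_set(200, n_ch = 2, n_t = 16, seed = 12)
  labels <- factor(c(rep("fast", 140), rep("medium", 44), rep("slow", 16)),
                   levels = c("fast", "medium", "slow", "outlier"))
  prm <- bootstrap_params(r = 8, alpha = c(fast = 0.3, medium = 0.2, slow = 0.1),
                          n = 300, n_alpha = 5, seed = 5)
  aug <- bootstrap_erps(ts, labels, prm)
  share_before <- mean(labels == "slow")
  share_after <- mean(aug$category == "slow")
  expect_gt(share_after, share_before)
})

test_that("eigenspace residuals match a direct SVD reconstruction oracle", {
  ts <- tiny_trial_set(12, n_ch = 3, n_t = 15, seed = 7)
  aug_raw <- tiny_trial_set(20, n_ch = 3, n_t = 15, seed = 8)
  aug <- augmented_erp_set(aug_raw$data, rep("fast", 20), rep("S01", 20),
                           rep(5L, 20))
  k <- 4
  filt <- eigenspace_filter(ts, aug, k = k, lo = 0, hi = 100)
  resid <- attr(filt, "all_residuals")
  # oracle: svd of the centered raw matrix, explicit reconstruction
  X <- matrix(ts$data, 12, 45)
  mu <- colMeans(X)
  sv <- svd(sweep(X, 2, mu))
  V <- sv$v[, seq_len(k)]
  A <- sweep(matrix(aug$erps, 20, 45), 2, mu)
  recon <- A %*% V %*% t(V)
  oracle <- sqrt(rowSums((A - recon)^2))
  expect_equal(resid, oracle, tolerance = 1e-8)
})

test_that("a sample inside the raw span has zero residual at full rank", {
  ts <- tiny_trial_set(10, n_ch = 2, n_t = 12, seed = 9)
  aug <- augmented_erp_set(ts$data[c(3, 5), , , drop = FALSE], rep("fast", 2),
                           rep("S01", 2), rep(1L, 2))
  filt <- eigenspace_filter(ts, aug, k = 9, lo = 0, hi = 100)
  expect_lt(max(attr(filt, "all_residuals")), 1e-8)
})

test_that("residual norms are non-increasing in the basis size", {
  ts <- tiny_trial_set(15, n_ch = 2, n_t = 12, seed = 10)
  aug_raw <- tiny_trial_set(8, n_ch = 2, n_t = 12, seed = 11)
  aug <- augmented_erp_set(aug_raw$data, rep("slow", 8), rep("S01", 8), rep(2L, 8))
  res <- sapply(1:8, function(k) {
    attr(eigenspace_filter(ts, aug, k = k, lo = 0, hi = 100), "all_residuals")
  })
  for (i in seq_len(nrow(res))) {
    expect_true(all(diff(res[i, ]) <= 1e-9))
  }
})

test_that("percentile filtering keeps the central half with inclusive stable order", {
  ts <- tiny_trial_set(10, n_ch = 2, n_t = 10, seed = 13)
  aug_raw <- tiny_trial_set(40, n_ch = 2, n_t = 10, seed = 14)
  aug <- augmented_erp_set(aug_raw$data, rep("fast", 40), rep("S01", 40),
                           rep(3L, 40))
  filt <- eigenspace_filter(ts, aug, k = 5, lo = 25, hi = 75)
  expect_equal(dim(filt$erps)[1], 20L)
  kept <- which(attr(filt, "retained"))
  expect_identical(kept, sort(kept)) # stable order
  # k larger than the raw rank is clipped with a warning
  expect_warning(eigenspace_filter(ts, aug, k = 50, lo = 25, hi = 75), "clipped")
})

test_that("share bookkeeping arithmetic reproduces printed-style proportions", {
  out <- category_share_table(c(slow = 90, medium = 240, fast = 670))
  expect_equal(out$total, 1000)
  expect_equal(unname(out$share_pct), c(9, 24, 67))
})
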