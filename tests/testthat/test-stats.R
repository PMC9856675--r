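# reduced model for single-cell tables (electrode/band constant)
factorial_anova_oneway <- function(tab) {
  m <- lm(activation ~ category, tab, contrasts = list(category = contr.sum))
  a <- car::Anova(m, type = 3)
  data.frame(effect = "category", F = a$`F value`[2], df1 = a$Df[2],
             df2 = m$df.residual, p = a$`Pr(>F)`[2])
}

test_that("a one-way balanced two-group design reproduces the textbook F ratio", {
  withr::with_seed(40, {
    g1 <- rnorm(12, 5); g2 <- rnorm(12, 6)
  })
  tab <- data.frame(
    sample = seq_len(24), subject = "S01",
    category = rep(c("fast", "slow"), each = 12),
    electrode = "E01", band = "alpha",
    activation = c(g1, g2)
  )
  # closed form: F = MS_between / MS_within
  gm <- mean(c(g1, g2))
  msb <- 12 * sum((c(mean(g1), mean(g2)) - gm)^2) / 1
  msw <- (sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)) / 22
  m <- lm(activation ~ category, tab)
  a <- anova(m)
  expect_equal(a$`F value`[1], msb / msw, tolerance = 1e-9)
  # the same value flows through the package's category main effect
  fa <- suppressWarnings(factorial_anova_oneway(tab))
  expect_equal(fa$F[fa$effect == "category"], msb / msw, tolerance = 1e-9)
})

test_that("the factorial model reports all seven effects and flags empty cells", {
  tab <- null_activation_table(n_per_cat = 4, n_electrodes = 4, seed = 44)
  a <- factorial_anova(tab, random_intercept = "none")
  expect_setequal(a$effect,
                  c("electrode", "band", "category", "electrode:band",
                    "electrode:category", "band:category",
                    "electrode:band:category"))
  expect_true(all(a$F >= 0))
  expect_true(all(a$df1 >= 1))
  bad <- tab[!(tab$electrode == "E01" & tab$band == "alpha" & tab$category == "fast"), ]
  expect_error(factorial_anova(bad, random_intercept = "none"), "empty cell")
})

test_that("the mixed model with a per-sample intercept tests category between samples", {
  tab <- null_activation_table(n_per_cat = 4, n_electrodes = 4, seed = 45)
  # genuine per-sample level shifts, the structure the random intercept models
  withr::with_seed(52, {
    shift <- rnorm(length(unique(tab$sample)), 0, 2)
  })
  tab$activation <- tab$activation + shift[tab$sample]
  a <- factorial_anova(tab, random_intercept = "sample")
  # category varies between samples only: its denominator df is close to the
  # number of samples, far below the row count
  df_cat <- a$df2[a$effect == "category"]
  expect_lt(df_cat, 30)
  expect_gt(a$df2[a$effect == "electrode"], 60)
})

test_that("balanced sums of squares decompose the total variance", {
  tab <- null_activation_table(n_per_cat = 3, n_electrodes = 3, seed = 46)
  m <- lm(activation ~ electrode * band * category, data = tab)
  a <- anova(m)
  total <- sum((tab$activation - mean(tab$activation))^2)
  expect_equal(sum(a$`Sum Sq`), total, tolerance = 1e-6 * total)
})

test_that("identical groups give near-unit adjusted p and near-zero z ratio", {
  withr::with_seed(47, v <- rnorm(30))
  tab <- data.frame(sample = 1:60, subject = "S", category = rep(c("fast", "slow"), each = 30),
                    electrode = "E01", band = "alpha", activation = c(v, v))
  pc <- tukey_contrasts(tab)
  expect_gt(pc$p_adj[1], 0.99)
  expect_lt(abs(pc$z_ratio[1]), 1e-9)
})

test_that("Tukey z ratios match the pooled-variance hand computation", {
  withr::with_seed(48, {
    a <- rnorm(10, 1); b <- rnorm(12, 2); c <- rnorm(9, 4)
  })
  tab <- data.frame(
    sample = seq_len(31), subject = "S",
    category = c(rep("fast", 10), rep("medium", 12), rep("slow", 9)),
    electrode = "E01", band = "alpha", activation = c(a, b, c)
  )
  pc <- tukey_contrasts(tab, electrode = "E01", band = "alpha")
  s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2) + sum((c - mean(c))^2)) / (31 - 3)
  z_fm <- (mean(a) - mean(b)) / sqrt(s2 * (1 / 10 + 1 / 12))
  z_fs <- (mean(a) - mean(c)) / sqrt(s2 * (1 / 10 + 1 / 9))
  z_ms <- (mean(b) - mean(c)) / sqrt(s2 * (1 / 12 + 1 / 9))
  expect_equal(pc$z_ratio, c(z_fm, z_fs, z_ms), tolerance = 1e-6)
  # the family follows the fast-med / fast-slow / med-slow pattern
  expect_equal(pc$contrast, c("fast - medium", "fast - slow", "medium - slow"))
  # Tukey-adjusted p is never smaller than the unadjusted p
  p_unadj <- 2 * pt(-abs(pc$z_ratio), 31 - 3)
  expect_true(all(pc$p_adj >= p_unadj - 1e-12))
})

test_that("posthoc contrasts require at least two populated categories", {
  tab <- data.frame(sample = 1:5, subject = "S", category = "fast",
                    electrode = "E01", band = "alpha", activation = rnorm(5))
  expect_error(tukey_contrasts(tab), "at least 2")
  tab2 <- rbind(tab, data.frame(sample = 6, subject = "S", category = "slow",
                                electrode = "E01", band = "alpha", activation = 1))
  expect_error(tukey_contrasts(tab2), "singleton")
})

test_that("well-separated trimodal activations are recovered as exact tiers", {
  withr::with_seed(49, {
    mu <- c(rep(1, 20), rep(5, 24), rep(10, 20)) + rnorm(64, 0, 0.1)
  })
  tab <- data.frame(sample = 1, subject = "S", category = "fast",
                    electrode = sprintf("E%02d", 1:64), band = "alpha",
                    activation = mu)
  r <- rank_activations(tab, seed = 3)
  expect_equal(unname(table(r$tier)[c("low", "relevant", "high")]),
               c(20L, 24L, 20L), ignore_attr = TRUE)
  expect_true(all(r$tier[mu > 8] == "high"))
  expect_true(all(r$tier[mu < 2] == "low"))
})

test_that("degenerate all-equal activations are rejected by the ranking", {
  tab <- data.frame(sample = 1, subject = "S", category = "fast",
                    electrode = sprintf("E%02d", 1:64), band = "alpha",
                    activation = rep(2, 64))
  expect_error(rank_activations(tab), "distinct")
})

test_that("report strings render in the F(df1, df2) style", {
  rep <- structure(data.frame(effect = "electrode", F = 7.49, df1 = 63,
                              df2 = 13637, p = 1e-16),
                   class = c("anova_report", "data.frame"))
  expect_match(format_anova(rep), "electrode: F\\(63, 13637\\) = 7.49")
})
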