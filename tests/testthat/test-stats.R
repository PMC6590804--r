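test_that("sign-flip permutation test handles identity and degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  r <- perm_paired_t(x, x, n_perm = 500, seed = 1)
  expect_equal(r$t, 0)
  expect_equal(r$p_perm, 1)
  expect_true(r$degenerate)
  r2 <- perm_paired_t(x, x - 2, n_perm = 500, seed = 1)
  expect_false(r2$degenerate)
  expect_gte(r2$p_perm, 1 / 501)
  expect_lte(r2$p_perm, 1)
  r3 <- perm_paired_t(x, x - 2, n_perm = 500, seed = 1)
  expect_identical(r2$p_perm, r3$p_perm)  # seed determinism
})

test_that("sampled permutation p matches exhaustive enumeration at n = 8", {
  set.seed(30)
  for (i in 1:5) {
    d <- rnorm(8, mean = 0.6)
    exact <- perm_exact_p(d)
    r <- perm_paired_t(d, rep(0, 8), n_perm = 2000, seed = 40 + i)
    se <- sqrt(exact * (1 - exact) / 2000)
    expect_lt(abs(r$p_perm - exact), 3 * se + 2 / 2000)
  }
})

test_that("permutation t equals the classical paired t statistic", {
  set.seed(31)
  x <- rnorm(10); y <- rnorm(10)
  r <- perm_paired_t(x, y, n_perm = 100, seed = 2)
  expect_equal(r$t, unname(stats::t.test(x, y, paired = TRUE)$statistic),
               tolerance = 1e-12)
})

test_that("BH adjustment matches the hand-computed step-up on fixed and random input", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_identical(fdr_adjust(numeric(0)), numeric(0))
  set.seed(32)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))^sample(1:3, 1)
    a <- fdr_adjust(p)
    expect_equal(a, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(a >= p - 1e-15))
    o <- order(p)
    expect_true(all(diff(a[o]) >= -1e-15))  # monotone in rank order
  }
})

test_that("unpaired t matches the closed-form Welch computation", {
  x <- c(19.8, 20.4, 19.6, 17.8, 18.5, 18.9, 18.3, 18.9, 19.5, 22.0)
  y <- c(28.2, 26.6, 20.1, 23.3, 25.2, 22.1, 17.7, 27.6, 20.6, 13.7)
  r <- unpaired_t(x, y)
  se <- sqrt(var(x) / 10 + var(y) / 10)
  t_hand <- (mean(x) - mean(y)) / se
  df_hand <- se^4 / ((var(x) / 10)^2 / 9 + (var(y) / 10)^2 / 9)
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_equal(r$df, df_hand, tolerance = 1e-10)
  expect_equal(r$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)
  expect_true(unpaired_t(x, x)$t == 0)
  expect_true(unpaired_t(rep(1, 3), rep(1, 4))$degenerate)
  big <- unpaired_t(rnorm(200), rnorm(200) + 5)
  expect_lt(big$p, 1e-3)
})

test_that("within-subject ANOVA reproduces the aov error-strata decomposition", {
  set.seed(33)
  for (i in 1:25) {
    ns <- sample(4:7, 1)
    df <- expand.grid(subject = seq_len(ns), A = paste0("a", 1:4),
                      B = paste0("b", 1:3))
    df$y <- rnorm(nrow(df)) + rnorm(ns)[df$subject] +
      (df$A == "a2") * rnorm(1) + (df$B == "b3") * rnorm(1)
    mine <- rm_anova(df, "y", subject = "subject", factor_a = "A",
                     factor_b = "B")
    oracle <- aov_oracle(df, "y")
    expect_equal(mine$F, unname(oracle[, "F"]), tolerance = 1e-8)
    expect_equal(mine$p, unname(oracle[, "p"]), tolerance = 1e-8)
    expect_equal(mine$df_num, c(3, 2, 6))
    expect_equal(mine$df_den, c(3, 2, 6) * (ns - 1))
  }
})

test_that("ANOVA degenerate inputs give flat F or informative errors", {
  df <- expand.grid(subject = 1:6, A = c("x", "y"), B = c("u", "v", "w"))
  df$y <- 1
  r <- rm_anova(df, "y", factor_a = "A", factor_b = "B")
  expect_true(all(is.na(r$F) | r$F < 1e-10))
  expect_error(rm_anova(df[df$subject == 1, ], "y", factor_a = "A",
                        factor_b = "B"), ">= 2 subjects")
  expect_error(rm_anova(df[-1, ], "y", factor_a = "A", factor_b = "B"),
               "missing cell")
  expect_match(tryCatch(rm_anova(df[-1, ], "y", factor_a = "A", factor_b = "B"),
                        error = conditionMessage), "\\(1, x, u\\)")
})

test_that("trial-level rows are averaged into subject cell means first", {
  set.seed(34)
  df <- expand.grid(rep = 1:5, subject = 1:4, A = c("x", "y"),
                    B = c("u", "v"))
  df$y <- rnorm(nrow(df))
  cm <- stats::aggregate(y ~ subject + A + B, df, mean)
  expect_equal(rm_anova(df, "y", factor_a = "A", factor_b = "B")$F,
               rm_anova(cm, "y", factor_a = "A", factor_b = "B")$F,
               tolerance = 1e-12)
})

test_that("Bonferroni post-hocs are capped pairwise paired t-tests", {
  set.seed(35)
  df <- expand.grid(subject = 1:8, distance = c("p0", "p1", "p2"))
  df$y <- rnorm(24) + 2 * (df$distance == "p2")
  ph <- posthoc_bonferroni(df, "y")
  expect_equal(nrow(ph), 3)
  m <- tapply(df$y, list(df$subject, df$distance), mean)
  tt <- stats::t.test(m[, "p0"], m[, "p1"], paired = TRUE)
  i <- ph$level_1 == "p0" & ph$level_2 == "p1"
  expect_equal(ph$t[i], unname(tt$statistic), tolerance = 1e-12)
  expect_equal(ph$p_bonf[i], min(1, tt$p.value * 3), tolerance = 1e-12)
  expect_true(all(ph$p_bonf >= ph$p_raw))
  same <- expand.grid(subject = 1:5, distance = c("p0", "p1"))
  same$y <- same$subject * 1.0
  ph2 <- posthoc_bonferroni(same, "y")
  expect_equal(ph2$p_bonf, 1)
  expect_error(posthoc_bonferroni(same[same$distance == "p0", ], "y"),
               "2 factor levels")
})
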