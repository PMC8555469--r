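test_that("median split excludes the median subject and balances groups", {
  g <- median_split(c(a = 60, b = 65, c = 70, d = 75, e = 80))
  expect_equal(g$excluded, "c")
  expect_setequal(g$assignment$subject_id[g$assignment$group == "Low"],
                  c("a", "b"))
  expect_setequal(g$assignment$subject_id[g$assignment$group == "High"],
                  c("d", "e"))
  # even n, no observation at the median: nobody excluded
  g2 <- median_split(c(1, 2, 3, 4))
  expect_length(g2$excluded, 0L)
  expect_equal(sum(g2$assignment$group == "High"), 2L)
  expect_error(median_split(rep(70, 5)), "identical")
  expect_error(median_split(c(1, 2)), "at least 3")
})

test_that("permutation ANOVA F statistics agree with the classical fit", {
  set.seed(60)
  df <- expand.grid(subject = sprintf("P%02d", 1:20),
                    hand = c("left", "right"), stringsAsFactors = FALSE)
  df$group <- rep(c("High", "Low"), each = 10)[match(df$subject,
                                                     sprintf("P%02d", 1:20))]
  df$value <- rnorm(40) + (df$group == "High") * 0.8
  res <- perm_anova_2x2(df, n_perm = 99, seed = 1)
  ref <- anova(lm(value ~ group * hand, data = df))
  expect_equal(res$F_obs[res$effect == "group"],
               ref["group", "F value"], tolerance = 1e-10)
  expect_equal(res$F_obs[res$effect == "hand"],
               ref["hand", "F value"], tolerance = 1e-10)
  expect_equal(res$F_obs[res$effect == "interaction"],
               ref["group:hand", "F value"], tolerance = 1e-10)
  expect_equal(res$df2[1], 36)
})

test_that("permutation p-values respect the (b+1)/(B+1) convention and the seed", {
  # overwhelming group effect: observed F beats every permutation
  df <- expand.grid(subject = sprintf("P%02d", 1:20),
                    hand = c("left", "right"), stringsAsFactors = FALSE)
  df$group <- rep(c("High", "Low"), each = 10)[match(df$subject,
                                                     sprintf("P%02d", 1:20))]
  set.seed(61)
  df$value <- rnorm(40, sd = 0.01) + (df$group == "High") * 100
  res <- perm_anova_2x2(df, n_perm = 999, seed = 2)
  expect_equal(res$p_perm[res$effect == "group"], 1 / 1000)
  a <- perm_anova_2x2(df, n_perm = 199, seed = 7)
  b <- perm_anova_2x2(df, n_perm = 199, seed = 7)
  expect_identical(a$p_perm, b$p_perm)
  # restricted subject-level scheme agrees on the observed statistics
  s <- perm_anova_2x2(df, n_perm = 199, seed = 7, scheme = "subject")
  expect_equal(s$F_obs, a$F_obs, tolerance = 1e-10)
  expect_lt(s$p_perm[s$effect == "group"], 0.05)
  bad <- df[df$group == "High" | df$hand == "left", ]
  expect_error(perm_anova_2x2(bad, n_perm = 9), "empty cell")
  expect_error(perm_anova_2x2(df, n_perm = 0), "n_perm")
})

test_that("permutation t-test matches the exhaustive relabeling tail", {
  # a = {0,0,0}, b = {1,1,1}: enumerate all C(6,3) = 20 relabelings
  a <- c(0, 0, 0); b <- c(1, 1, 1)
  pool <- c(a, b)
  combos <- combn(6, 3)
  welch <- function(x, y) {
    se2 <- var(x) / 3 + var(y) / 3
    d <- mean(x) - mean(y)
    if (se2 == 0) return(if (d == 0) 0 else sign(d) * Inf)
    d / sqrt(se2)
  }
  t_obs <- welch(a, b)
  exact <- mean(apply(combos, 2, function(ix) {
    abs(welch(pool[ix], pool[-ix])) >= abs(t_obs)
  }))
  expect_equal(exact, 0.1)  # only the two perfect separations tie |t| = Inf
  res <- perm_ttest(a, b, n_perm = 1999, seed = 3)
  expect_lt(abs(res$p_perm - exact), 0.03)
  # identical samples: t = 0, p = 1
  same <- perm_ttest(c(1, 2, 3), c(1, 2, 3), n_perm = 99, seed = 4)
  expect_equal(same$t_obs, 0)
  expect_equal(same$p_perm, 1)
  expect_error(perm_ttest(1, c(1, 2)), ">= 2")
})

test_that("permutation t-test is calibrated under the null", {
  set.seed(62)
  rej <- vapply(1:400, function(r) {
    perm_ttest(rnorm(10), rnorm(10), n_perm = 99)$p_perm <= 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
})

test_that("Bonferroni threshold is alpha over m", {
  expect_equal(bonferroni(0.05, 6), 0.05 / 6)
  expect_equal(round(bonferroni(0.05, 6), 3), 0.008)
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_equal(bonferroni(0.01, 2), 0.005)
  expect_error(bonferroni(0.05, 0), "m")
})
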