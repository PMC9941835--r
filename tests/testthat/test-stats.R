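test_that("extra sum-of-squares F statistic matches hand arithmetic", {
  # ((10-5)/2) / (5/10) = 5
  ft <- ess_f_test(10, 12, 5, 10)
  expect_equal(ft$f, 5)
  expect_equal(ft$df_num, 2)
  expect_equal(ft$df_den, 10)
  expect_equal(ft$p, stats::pf(5, 2, 10, lower.tail = FALSE))
  # equal fits: F = 0, p = 1
  ft0 <- ess_f_test(5, 12, 5, 10)
  expect_equal(ft0$f, 0)
  expect_equal(ft0$p, 1)
  expect_error(ess_f_test(10, 10, 5, 10), "degrees of freedom")
  expect_error(ess_f_test(4, 12, 5, 10), ">=")
})

test_that("ess_f_test reproduces anova() on randomized nested linear fits", {
  withr::with_seed(123, {
    for (case in 1:100) {
      n <- sample(12:40, 1)
      x1 <- rnorm(n); x2 <- rnorm(n)
      y <- 1 + 0.5 * x1 + rnorm(n) * runif(1, 0.5, 2) +
        sample(c(0, 0.8), 1) * x2
      full <- stats::lm(y ~ x1 + x2)
      red <- stats::lm(y ~ x1)
      ref <- stats::anova(red, full)
      ft <- ess_f_test(sum(stats::resid(red)^2), red$df.residual,
                       sum(stats::resid(full)^2), full$df.residual)
      expect_equal(ft$f, ref$F[2], tolerance = 1e-10)
      expect_equal(ft$p, ref$`Pr(>F)`[2], tolerance = 1e-10)
    }
  })
})

test_that("one-way ANOVA with Bonferroni behaves classically", {
  withr::with_seed(5, {
    d <- data.frame(value = c(rnorm(8), rnorm(8)), group = rep(c("a", "b"), each = 8))
    # identical groups (same distribution within variance): F small; exact
    # identity case: duplicate one group
    d2 <- data.frame(value = rep(d$value[d$group == "a"], 2),
                     group = rep(c("a", "b"), each = 8))
    cmp2 <- anova_bonferroni(d2, "value", "group")
    expect_equal(cmp2$omnibus$f, 0, tolerance = 1e-12)
    expect_equal(cmp2$omnibus$p, 1, tolerance = 1e-12)
    # two groups: omnibus F equals the squared pooled t statistic
    cmp <- anova_bonferroni(d, "value", "group")
    tt <- stats::t.test(value ~ group, data = d, var.equal = TRUE)
    expect_equal(cmp$omnibus$f, unname(tt$statistic)^2, tolerance = 1e-10)
    # adjusted p-values: never below raw, capped at 1, monotone in raw
    d3 <- data.frame(value = rnorm(30), group = rep(letters[1:3], 10))
    cmp3 <- anova_bonferroni(d3, "value", "group")
    expect_true(all(cmp3$pairwise$p_adj >= cmp3$pairwise$p_raw))
    expect_true(all(cmp3$pairwise$p_adj <= 1))
    ord <- order(cmp3$pairwise$p_raw)
    expect_true(all(diff(cmp3$pairwise$p_adj[ord]) >= -1e-12))
  })
  expect_error(anova_bonferroni(data.frame(value = c(1, 1, 2, 2),
                                           group = c("a", "a", "b", "b"))),
               "zero within-group variance")
})

test_that("group separation at published effect sizes is detected reliably", {
  # WT vs mutant activation V0.5 at the published means and SEMs
  # (n = 13 each): the difference is significant at alpha = 0.001 in at
  # least 95% of replicates
  withr::with_seed(99, {
    hits <- vapply(1:200, function(i) {
      wt <- rnorm(13, -0.12, 1.32 * sqrt(13))
      mu <- rnorm(13, -28.5, 1.48 * sqrt(13))
      d <- data.frame(value = c(wt, mu), group = rep(c("wt", "mut"), each = 13))
      anova_bonferroni(d, "value", "group")$pairwise$p_adj[1] < 0.001
    }, TRUE)
    expect_gte(mean(hits), 0.95)
  })
})

test_that("summarize_sem reports mean, SEM and n", {
  expect_equal(summarize_sem(c(1, 1, 1)), tibble::tibble(mean = 1, sem = 0, n = 3L))
  expect_equal(summarize_sem(c(0, 2)), tibble::tibble(mean = 1, sem = 1, n = 2L))
  withr::with_seed(2, {
    x <- rnorm(37)
    s <- summarize_sem(x)
    expect_equal(s$sem, stats::sd(x) / sqrt(37))
  })
})
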