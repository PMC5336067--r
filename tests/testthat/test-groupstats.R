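test_that("pooled t from summaries matches published two-group analyses", {
  ladder <- pooled_t_from_summary(group_summary(55.68, 21.96, 8),
                                  group_summary(53.99, 22.44, 8))
  expect_equal(round(ladder$F, 2), 0.02)
  expect_equal(round(ladder$p, 2), 0.88)
  expect_equal(ladder$df, 14L)
  boat <- pooled_t_from_summary(group_summary(75.64, 8.41, 8),
                                group_summary(119.83, 48.99, 8))
  expect_equal(round(boat$F, 2), 6.32)
  ident <- pooled_t_from_summary(group_summary(5, 2, 8),
                                 group_summary(5, 2, 8))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  expect_equal(ident$F, 0)
  # degenerate zero-variance equal means
  z <- pooled_t_from_summary(group_summary(3, 0, 8), group_summary(3, 0, 8))
  expect_equal(z$t, 0)
})

test_that("summary-path t equals the raw-path pooled t", {
  set.seed(71)
  for (i in 1:25) {
    x <- rnorm(8, 10, 3); y <- rnorm(8, 12, 3)
    s <- pooled_t_from_summary(group_summary(mean(x), sd(x), 8),
                               group_summary(mean(y), sd(y), 8))
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(s$t, unname(tt$statistic), tolerance = 1e-9)
    expect_equal(s$p, tt$p.value, tolerance = 1e-9)
  }
})

test_that("Levene test: degenerate, scale detection, cross-check", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  lv <- levene_test(x, x)
  expect_equal(lv$W, 0)
  set.seed(72)
  y <- rnorm(8)
  lv10 <- levene_test(y, 10 * y)
  expect_lt(lv10$p, 0.05)
  expect_false(lv10$equal)
  # cross-check against the established implementation (mean centring)
  skip_if_not_installed("car")
  set.seed(73)
  for (i in 1:10) {
    a <- rnorm(8); b <- rnorm(8, sd = runif(1, 0.5, 3))
    mine <- levene_test(a, b)
    ref <- car::leveneTest(c(a, b), factor(rep(1:2, each = 8)),
                           center = mean)
    expect_equal(mine$W, ref$`F value`[1], tolerance = 1e-9)
    expect_equal(mine$p, ref$`Pr(>F)`[1], tolerance = 1e-9)
  }
})

test_that("Levene type-I error is near nominal", {
  set.seed(74)
  rej <- mean(replicate(1000, {
    levene_test(rnorm(8), rnorm(8))$p <= 0.05
  }))
  expect_true(abs(rej - 0.05) <= 0.02)
})

test_that("ANOVA F equals t squared for two groups", {
  set.seed(75)
  for (i in 1:25) {
    x <- rnorm(8, 5); y <- rnorm(8, 6)
    a <- anova_oneway(list(x, y))
    tt <- pooled_t_from_summary(group_summary(mean(x), sd(x), 8),
                                group_summary(mean(y), sd(y), 8))
    expect_equal(a$F, tt$t^2, tolerance = 1e-9)
  }
  id <- anova_oneway(list(rep(2, 4), rep(2, 4)))
  expect_equal(id$F, 0)
})

test_that("Kruskal-Wallis H matches the hand-computed rank example", {
  # groups {1,2,3},{4,5,6},{7,8,9}: ranks 1..9, rank sums 6, 15, 24:
  # H = 12/(9*10) * (36/3 + 225/3 + 576/3) - 3*10 = 7.2
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$H, 7.2, tolerance = 1e-9)
  expect_equal(kw$df, 2L)
  id <- kruskal_wallis(list(rep(1, 4), rep(1, 4)))
  expect_equal(id$H, 0)
})

test_that("percent differences reproduce the published table", {
  expect_equal(percent_difference(55.68, 53.99), -3L)
  expect_equal(percent_difference(81, 53), -35L)
  expect_equal(percent_difference(123.75, 200.63), 62L)
  expect_equal(percent_difference(5, 1.63), -67L)
  expect_equal(percent_difference(4, 4), 0L)
  expect_error(percent_difference(0, 1), "zero")
})

test_that("critical values match the t and F tables", {
  cv <- critical_values(0.05, 1, 14)
  expect_equal(round(cv$t_crit, 2), 1.76)
  expect_equal(round(cv$F_crit, 1), 4.6)
  # distributional identity F(1, df) = t^2 two-tailed
  set.seed(76)
  for (df in sample(3:60, 10)) {
    cv <- critical_values(0.05, 1, df)
    expect_equal(cv$F_crit, qt(0.975, df)^2, tolerance = 1e-9)
  }
  expect_error(critical_values(1.5), "alpha")
  expect_error(critical_values(0.05, 0, 4), "degrees")
})

test_that("compare_groups builds a full gated report", {
  set.seed(77)
  outcomes <- rbind(
    data.frame(subject = paste0("c", 1:8), group = "control",
               metric = "time", value = rnorm(8, 60, 10)),
    data.frame(subject = paste0("t", 1:8), group = "target",
               metric = "time", value = rnorm(8, 110, 12)))
  rep <- compare_groups(outcomes)
  expect_s3_class(rep, "group_comparison")
  expect_equal(rep$verdict, "different")
  expect_equal(rep$F, rep$t^2, tolerance = 1e-9)
  expect_output(print(rep), "Diff")
  # single-subject group errors
  bad <- outcomes[-(1:7), ]
  expect_error(compare_groups(bad), "at least 2")
})

test_that("weak Levene outcomes are flagged", {
  # construct samples whose Levene p lands in (0.05, 0.10]
  found <- FALSE
  set.seed(78)
  for (i in 1:500) {
    a <- rnorm(8); b <- rnorm(8, sd = 2.2)
    p <- levene_test(a, b)$p
    if (p > 0.05 && p <= 0.10) {
      outc <- rbind(data.frame(subject = paste0("c", 1:8), group = "control",
                               metric = "m", value = a),
                    data.frame(subject = paste0("t", 1:8), group = "target",
                               metric = "m", value = b))
      expect_true(compare_groups(outc)$levene_weak)
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("the gated pipeline holds its type-I error near 5 %", {
  set.seed(79)
  rej <- mean(replicate(1000, {
    a <- rnorm(8); b <- rnorm(8)
    lv <- levene_test(a, b)
    tt <- pooled_t_from_summary(group_summary(mean(a), sd(a), 8),
                                group_summary(mean(b), sd(b), 8))
    kw <- kruskal_wallis(list(a, b))
    if (lv$equal) tt$p < 0.05 && kw$p_chi_sq < 0.05 else kw$p_chi_sq < 0.05
  }))
  expect_true(abs(rej - 0.05) <= 0.02)
})

test_that("equal cohorts are judged equal, shifted cohorts different", {
  set.seed(80)
  verdict_null <- replicate(60, {
    outc <- rbind(data.frame(subject = paste0("c", 1:8), group = "control",
                             metric = "m", value = rnorm(8, 70, 10)),
                  data.frame(subject = paste0("t", 1:8), group = "target",
                             metric = "m", value = rnorm(8, 70, 10)))
    compare_groups(outc)$verdict
  })
  expect_gt(mean(verdict_null == "equal"), 0.85)
  verdict_shift <- replicate(60, {
    outc <- rbind(data.frame(subject = paste0("c", 1:8), group = "control",
                             metric = "m", value = rnorm(8, 70, 10)),
                  data.frame(subject = paste0("t", 1:8), group = "target",
                             metric = "m", value = rnorm(8, 112, 14)))
    compare_groups(outc)$verdict
  })
  expect_gt(mean(verdict_shift == "different"), 0.5)
})

test_that("published study summaries are available for re-analysis", {
  tab <- exergame_study_summaries()
  expect_equal(nrow(tab), 5L)
  expect_true(all(tab$n == 8))
  row <- tab[tab$metric == "ladder_time_s", ]
  res <- pooled_t_from_summary(
    group_summary(row$control_mean, row$control_sd, row$n),
    group_summary(row$target_mean, row$target_sd, row$n))
  expect_equal(round(res$F, 2), 0.02)
})
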