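test_that("arcsine square-root transform hits its endpoints", {
  expect_equal(arcsine_sqrt(0), 0)
  expect_equal(arcsine_sqrt(1), pi / 2)
  expect_equal(arcsine_sqrt(0.25), pi / 6)
  expect_error(arcsine_sqrt(1.1), "0, 1")
  expect_error(arcsine_sqrt(-0.1), "0, 1")
})

test_that("one-way ANOVA reproduces the hand decomposition", {
  y <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  g <- rep(c("a", "b", "c"), each = 3)
  an <- one_way_anova(y, g)
  # SSB = 6, SSW = 6 -> F = (6/2)/(6/6) = 3 on (2, 6) df
  expect_equal(an$F, 3)
  expect_equal(an$df, c(2, 6))
  expect_equal(an$p, stats::pf(3, 2, 6, lower.tail = FALSE))
  # identical group means -> F = 0
  an0 <- one_way_anova(c(1, 2, 1, 2), c("a", "a", "b", "b"))
  expect_equal(an0$F, 0)
  # all responses identical -> degenerate, not a number
  and <- one_way_anova(rep(2, 6), rep(c("a", "b"), 3))
  expect_true(and$degenerate)
  expect_true(is.na(and$F))
  # survey-sized design: 40 observations, 2 levels -> df (1, 38)
  set.seed(5)
  an40 <- one_way_anova(rnorm(40), rep(c("f", "m"), each = 20))
  expect_equal(an40$df, c(1, 38))
  expect_error(one_way_anova(1:4, rep("a", 4)), "two")
})

test_that("ANOVA F matches a two-pass sums-of-squares oracle", {
  set.seed(101)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    sizes <- sample(2:8, k, replace = TRUE)
    g <- factor(rep(seq_len(k), sizes))
    y <- rnorm(sum(sizes), mean = as.integer(g) * runif(1))
    an <- one_way_anova(y, g)
    gm <- mean(y)
    means <- tapply(y, g, mean)
    ssb <- sum(sizes * (means - gm)^2)
    ssw <- sum((y - means[as.integer(g)])^2)
    f_oracle <- (ssb / (k - 1)) / (ssw / (sum(sizes) - k))
    expect_equal(an$F, f_oracle, tolerance = 1e-10)
  }
})

test_that("ANOVA holds its nominal type-I error under the null", {
  set.seed(2024)
  n_rep <- 2000
  rej <- 0L
  g <- factor(rep(1:4, each = 10))
  for (i in seq_len(n_rep)) {
    y <- rnorm(40)
    fit <- stats::lm(y ~ g)
    p <- stats::anova(fit)[["Pr(>F)"]][1]
    rej <- rej + (p < 0.05)
  }
  expect_lt(abs(rej / n_rep - 0.05), 0.02)
})

test_that("Tukey-Kramer comparisons agree with the reference route", {
  set.seed(7)
  # unbalanced sizes mirroring the survey's migration groups
  g <- factor(rep(c("no_young", "no_old", "temp", "perm"),
                  c(8, 20, 6, 6)))
  y <- rnorm(40, mean = c(0, 0.5, 0, 1)[as.integer(g)])
  tk <- tukey_hsd(y, g)
  ref <- stats::TukeyHSD(stats::aov(y ~ g))$g
  # align pair order by label
  lab <- rownames(ref)
  tk <- tk[match(lab, gsub(" ", "", tk$pair)), ]
  expect_equal(tk$diff, unname(ref[, "diff"]), tolerance = 1e-10)
  expect_equal(tk$p_adj, unname(ref[, "p adj"]), tolerance = 1e-8)
})

test_that("with two groups the studentized range reduces to sqrt(2)|t|", {
  set.seed(13)
  y <- rnorm(20)
  g <- factor(rep(c("a", "b"), each = 10))
  tk <- tukey_hsd(y, g)
  tt <- stats::t.test(y ~ g, var.equal = TRUE)
  expect_equal(tk$q, sqrt(2) * abs(unname(tt$statistic)),
               tolerance = 1e-10)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-8)
})

test_that("Tukey-adjusted p-values are conservative", {
  set.seed(23)
  for (i in 1:10) {
    g <- factor(rep(1:3, each = 7))
    y <- rnorm(21, mean = as.integer(g) * 0.4)
    tk <- tukey_hsd(y, g)
    msw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / 18
    for (j in seq_len(nrow(tk))) {
      t_stat <- abs(tk$diff[j]) / sqrt(msw * (1 / 7 + 1 / 7))
      p_unadj <- 2 * stats::pt(t_stat, 18, lower.tail = FALSE)
      expect_gte(tk$p_adj[j] + 1e-12, p_unadj)
    }
  }
})

test_that("proportion chi-square matches the hand 2x2 computation", {
  # pooled p = 0.375 -> chi2 = 8/3
  t1 <- category_proportion_test(10, 20, 5, 20)
  expect_equal(t1$statistic, 8 / 3, tolerance = 1e-12)
  expect_equal(t1$p, stats::pchisq(8 / 3, 1, lower.tail = FALSE))
  # all-or-nothing: chi2 = n (p1-p2)^2 / (pbar (1-pbar)) = 40
  t2 <- category_proportion_test(20, 20, 0, 20)
  expect_equal(t2$statistic, 40, tolerance = 1e-12)
  # equal proportions -> no signal
  t3 <- category_proportion_test(6, 12, 8, 16)
  expect_equal(t3$statistic, 0, tolerance = 1e-12)
  expect_equal(t3$p, 1)
  # degenerate all-zero case
  t4 <- category_proportion_test(0, 10, 0, 12)
  expect_equal(t4$statistic, 0)
  expect_equal(t4$p, 1)
  expect_error(category_proportion_test(5, 4, 1, 10), "x <= n")
})

test_that("the proportion test is symmetric and label-invariant", {
  a <- category_proportion_test(7, 18, 3, 15)
  b <- category_proportion_test(3, 15, 7, 18)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p, b$p)
  # swapping successes and failures leaves chi-square unchanged
  c_ <- category_proportion_test(18 - 7, 18, 15 - 3, 15)
  expect_equal(a$statistic, c_$statistic, tolerance = 1e-12)
  # exact flavour agrees qualitatively
  e <- category_proportion_test(7, 18, 3, 15, method = "exact")
  expect_true(e$p >= 0 && e$p <= 1)
})

test_that("spearman correlation handles ties and monotone transforms", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(spearman_cor(x, x)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  s1 <- spearman_cor(x, x^3 + 2)
  expect_equal(s1$rho, 1)
  y <- c(2, 7, 1, 8, 2, 8, 1, 8)
  s2 <- spearman_cor(x, y)
  s3 <- spearman_cor(exp(x), y^5)
  expect_equal(s2$rho, s3$rho)
  expect_equal(s2$p, s3$p)
  expect_error(spearman_cor(1:3, 1:4), "mismatch")
  expect_error(spearman_cor(rep(1, 5), 1:5), "zero variance")
})

test_that("compare_groups screens every species and isolates degeneracy", {
  d <- tiny_data()
  res <- compare_groups(d, index = "salience", grouping = "sex")
  expect_equal(nrow(res), 3)
  expect_equal(res$df1, rep(1L, 3))
  expect_equal(res$df2, rep(2L, 3))
  expect_true(all(res$signif %in% c("ns", "*", "**", "***", NA)))
  # a species cited by nobody is degenerate but still reported
  d40 <- simulate_interviews(seed = 41)
  res40 <- compare_groups(d40, index = "salience", grouping = "sex")
  bec <- res40[res40$species == "BeC", ]
  if (salience_table(d40, "none")$n_cit[2] == 0) {
    expect_true(bec$degenerate)
    expect_true(is.na(bec$F))
  }
  expect_equal(res40$df2[1], 38L)
})

test_that("proportion_tests tabulates all pairs and categories", {
  d <- simulate_interviews(seed = 43)
  pt <- proportion_tests(d, "SM", grouping = "sex")
  expect_equal(nrow(pt), 9)
  expect_true(all(pt$n1 + pt$n2 == 40))
  pt_age <- proportion_tests(d, "SM", grouping = "age_class")
  expect_equal(nrow(pt_age), 9 * 6)
  expect_true(all(pt_age$x1 <= pt_age$n1 & pt_age$x2 <= pt_age$n2))
})
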