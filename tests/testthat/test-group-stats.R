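test_that("Dunnett with one contrast reduces to the pooled two-sample t-test", {
  set.seed(2)
  x <- rnorm(12, 0, 1)
  y <- rnorm(10, 0.7, 1)
  res <- dunnett_vs_control(c(x, y), rep(c("ctl", "trt"), c(12, 10)),
                            "ctl", mc_draws = 1e6, seed = 3)
  tt <- t.test(y, x, var.equal = TRUE)
  expect_lt(abs(res$p_adj - tt$p.value), 2e-3)
  expect_equal(res$estimate, mean(y) - mean(x), tolerance = 1e-12)
})

test_that("Dunnett agrees with the multivariate-t reference implementation", {
  set.seed(8)
  vals <- c(rnorm(8, 0), rnorm(8, 0.5), rnorm(8, 1.2), rnorm(8, -0.3))
  grp <- rep(c("ctl", "a", "b", "c"), each = 8)
  res <- dunnett_vs_control(vals, grp, "ctl", mc_draws = 5e5, seed = 4)
  d <- data.frame(y = vals, g = relevel(factor(grp), "ctl"))
  glht_fit <- multcomp::glht(stats::aov(y ~ g, data = d),
                             linfct = multcomp::mcp(g = "Dunnett"))
  ref <- summary(glht_fit)$test$pvalues
  # both orderings follow the non-control factor levels a, b, c
  expect_equal(res$p_adj, as.numeric(ref), tolerance = 0.01)
})

test_that("Dunnett rejects degenerate inputs", {
  expect_error(dunnett_vs_control(rep(1, 9), rep(c("a", "b", "c"), 3), "a"),
               "zero residual variance")
  expect_error(dunnett_vs_control(rnorm(6), rep(c("a", "b"), 3), "zz"),
               "control group")
  expect_error(dunnett_vs_control(c(1, 2, 3), c("a", "a", "b"), "a"),
               ">= 2 observations")
})

test_that("adjusted p-values are never below raw p-values", {
  set.seed(12)
  vals <- rnorm(30)
  grp <- rep(c("ctl", "a", "b"), each = 10)
  res <- dunnett_vs_control(vals, grp, "ctl", mc_draws = 5e4, seed = 2)
  expect_true(all(res$p_adj >= res$p_raw))
  expect_true(all(res$p_adj <= 1))
})

test_that("mixed-model slope contrast is exact on noiseless data", {
  d <- expand.grid(genotype = c("Col FRI", "slow"), day = c(10, 20, 30, 40),
                   block = 1:3, rep = 1:2, stringsAsFactors = FALSE)
  d$value_au <- ifelse(d$genotype == "Col FRI", 10 - 0.2 * d$day,
                       10 - 0.3 * d$day)
  res <- mixed_slope_contrasts(d, reference = "Col FRI")
  expect_equal(res$contrasts$estimate, -0.1, tolerance = 1e-6)
  expect_equal(res$contrasts$genotype, "slow")
})

test_that("with no block variance the mixed model matches OLS ANCOVA", {
  set.seed(21)
  d <- expand.grid(genotype = c("Col FRI", "g2", "g3"),
                   day = c(10, 20, 30, 40), block = 1:3,
                   stringsAsFactors = FALSE)
  slopes <- c("Col FRI" = -0.2, g2 = -0.25, g3 = -0.15)
  d$value_au <- 10 + slopes[d$genotype] * d$day + rnorm(nrow(d), 0, 0.2)
  res <- mixed_slope_contrasts(d, "Col FRI")
  dc <- transform(d, genotype = relevel(factor(genotype), "Col FRI"),
                  day_c = day - mean(day))
  ols <- lm(value_au ~ genotype * day_c, data = dc)
  ints <- coef(ols)[grepl(":day_c", names(coef(ols)))]
  expect_equal(res$contrasts$estimate, unname(ints), tolerance = 1e-6)
})

test_that("a single block falls back to fixed effects with a warning", {
  d <- expand.grid(genotype = c("a", "b"), day = c(10, 20, 30), block = 1,
                   rep = 1:3, stringsAsFactors = FALSE)
  set.seed(14)
  d$value_au <- 5 - 0.1 * d$day + rnorm(nrow(d), 0, 0.1)
  expect_warning(res <- mixed_slope_contrasts(d, "a"), "single block")
  expect_equal(res$method, "lm")
  expect_equal(res$varcomp[["block"]], 0)
})

test_that("Satterthwaite df and variance components are sane", {
  set.seed(33)
  d <- expand.grid(genotype = c("Col FRI", "g2"), day = c(10, 20, 30, 40),
                   block = 1:3, rep = 1:2, stringsAsFactors = FALSE)
  blk <- rnorm(3, 0, 0.5)
  d$value_au <- 10 - 0.2 * d$day + blk[d$block] + rnorm(nrow(d), 0, 0.2)
  res <- mixed_slope_contrasts(d, "Col FRI")
  expect_true(all(res$contrasts$df > 0))
  expect_true(all(res$varcomp >= 0))
  expect_equal(res$method, "lmer")
})

test_that("CV-equality statistic is zero for scale-equivalent groups", {
  res <- cv_equality_test(list(a = c(1, 2, 3), b = c(2, 4, 6)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 1)
})

test_that("CV-equality test is invariant to positive rescaling of a group", {
  set.seed(6)
  g1 <- rlnorm(15, 1, 0.3)
  g2 <- rlnorm(12, 2, 0.5)
  base <- cv_equality_test(list(g1, g2))
  scaled <- cv_equality_test(list(7.3 * g1, g2))
  expect_equal(scaled$statistic, base$statistic, tolerance = 1e-12)
  expect_equal(scaled$p_value, base$p_value, tolerance = 1e-12)
})

test_that("CV-equality test validates its inputs", {
  expect_error(cv_equality_test(list(c(1, 2))), ">= 2 numeric vectors")
  expect_error(cv_equality_test(list(a = c(1, 2), b = 3)), "n >= 2")
  expect_error(cv_equality_test(list(a = c(-1, 1), b = c(1, 2))),
               "mean of 0")
})

test_that("CV-equality test detects a genuine variability difference", {
  set.seed(41)
  # starting levels 5x more variable (cv) than rates, 10 genotypes
  rejections <- vapply(1:200, function(i) {
    starting <- rlnorm(10, log(10), 0.5)
    rates <- rlnorm(10, log(0.2), 0.1)
    cv_equality_test(list(starting = starting, rates = rates))$p_value < 0.01
  }, logical(1))
  expect_gte(mean(rejections), 0.95)
})

test_that("BH step-up matches the hand-worked example and handles edge cases", {
  res <- bh_adjust(c(0.01, 0.04, 0.03, 0.005), q = 0.05)
  expect_true(all(res$reject))  # p_(4) = 0.04 <= 0.05
  res2 <- bh_adjust(rep(1, 5), q = 0.05)
  expect_false(any(res2$reject))
  expect_equal(res2$p_adjusted, rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH equals the brute-force step-up definition on random inputs", {
  brute_bh <- function(p, q) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    ks <- which(ps <= seq_len(m) * q / m)
    reject <- rep(FALSE, m)
    if (length(ks)) reject[o[seq_len(max(ks))]] <- TRUE
    adj <- rev(cummin(rev(m * ps / seq_len(m))))
    adj <- pmin(adj, 1)
    list(reject = reject, adj = adj[order(o)])
  }
  set.seed(55)
  for (i in 1:200) {
    p <- runif(sample(1:20, 1))^sample(1:3, 1)
    ours <- bh_adjust(p, q = 0.05)
    ref <- brute_bh(p, 0.05)
    expect_identical(ours$reject, ref$reject)
    expect_equal(ours$p_adjusted, ref$adj, tolerance = 1e-12)
  }
})

test_that("variability report: identical features in two sites give p = 1", {
  f1 <- data.frame(genotype = paste0("g", 1:6), site = "Norwich",
                   year = 2016, starting_level = c(5, 8, 11, 14, 17, 20),
                   rate_vindep = -c(0.1, 0.12, 0.14, 0.16, 0.18, 0.2),
                   rate_vdep = -c(0.3, 0.31, 0.32, 0.33, 0.34, 0.35))
  f2 <- transform(f1, site = "North Sweden")
  rep_ <- variability_report(rbind(f1, f2))
  across <- rep_$tests[grepl("across site-years", rep_$tests$comparison), ]
  expect_true(all(abs(across$statistic) < 1e-12))
  expect_true(all(across$p == 1))
})

test_that("variability report is invariant to genotype label permutation", {
  set.seed(61)
  f <- data.frame(genotype = paste0("g", 1:8), site = "s", year = 1,
                  starting_level = rlnorm(8, 2, 0.4),
                  rate_vindep = -rlnorm(8, -2, 0.2),
                  rate_vdep = -rlnorm(8, -1, 0.1))
  a <- variability_report(f)
  f2 <- f
  f2$genotype <- sample(f2$genotype)
  b <- variability_report(f2)
  expect_equal(a$cv$cv, b$cv$cv)
  expect_equal(a$tests$p, b$tests$p)
})

test_that("variability report skips undersized groups with a log entry", {
  f <- data.frame(genotype = c("a", "b"), site = "s", year = 1,
                  starting_level = c(3, 4),
                  rate_vindep = c(-0.1, NA), rate_vdep = c(NA, NA))
  rep_ <- variability_report(f)
  expect_gt(nrow(rep_$skipped), 0)
})
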