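test_that("equal survival proportions give p = 1 without correction", {
  res <- survival_proportion_test(c(5, 10), c(5, 10))
  expect_equal(res$p_value, 1)
  expect_equal(res$prop_bolted, 0.5)
})

test_that("the survival test is symmetric in its arms", {
  a <- survival_proportion_test(c(12, 30), c(24, 36))
  b <- survival_proportion_test(c(24, 36), c(12, 30))
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
})

test_that("extreme tables agree with Fisher's exact test in conclusion", {
  chisq <- survival_proportion_test(c(0, 10), c(10, 10))
  fisher <- survival_proportion_test(c(0, 10), c(10, 10),
                                     method = "fisher")
  expect_lt(chisq$p_value, 1e-3)
  expect_lt(fisher$p_value, 1e-3)
  # contingency table: survivors vs deaths in each arm
  expect_equal(fisher$p_value,
               fisher.test(rbind(c(0, 10), c(10, 0)))$p.value)
})

test_that("survival test validates its arms", {
  expect_error(survival_proportion_test(c(5, 0), c(1, 2)), "n >= 1")
  expect_error(survival_proportion_test(c(5, 4), c(1, 2)), "successes")
})

test_that("rank test handles ties and small samples exactly", {
  expect_equal(rank_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  res <- rank_test(c(1, 2, 3), c(10, 20, 30))
  expect_true(res$exact)
  expect_equal(res$p_value, 0.1)  # 2/choose(6,3): the two extreme splits
  expect_equal(res$U, 0)
})

test_that("rank test is invariant to positive rescaling", {
  set.seed(3)
  x <- runif(6)
  y <- runif(7, 0.3, 1.3)
  a <- rank_test(x, y)
  b <- rank_test(5 * x, 5 * y)
  expect_equal(a$U, b$U)
  expect_equal(a$p_value, b$p_value)
})

test_that("exact branch equals an independent enumeration oracle", {
  # oracle counts U as #(x_i > y_j) + 0.5 #(x_i == y_j) over all
  # reassignments of the combined sample
  oracle <- function(x, y) {
    n1 <- length(x)
    comb <- c(x, y)
    u_of <- function(xs, ys)
      sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
    u_obs <- u_of(x, y)
    center <- n1 * length(y) / 2
    sets <- utils::combn(length(comb), n1)
    us <- apply(sets, 2, function(ix) u_of(comb[ix], comb[-ix]))
    mean(abs(us - center) >= abs(u_obs - center) - 1e-9)
  }
  set.seed(47)
  for (i in 1:10) {
    x <- sample(1:6, 5, replace = TRUE)
    y <- sample(1:6, 6, replace = TRUE)
    expect_equal(rank_test(x, y)$p_value, oracle(x, y))
  }
})

test_that("rank test agrees with wilcox.test where both are exact", {
  set.seed(53)
  x <- rnorm(7)
  y <- rnorm(8)
  ours <- rank_test(x, y)
  ref <- wilcox.test(x, y, exact = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(ours$U, unname(ref$statistic))
  # normal-approximation branch vs wilcox.test with correction
  x2 <- rnorm(15)
  y2 <- rnorm(16)
  ours2 <- rank_test(x2, y2)
  ref2 <- wilcox.test(x2, y2, exact = FALSE, correct = TRUE)
  expect_false(ours2$exact)
  expect_equal(ours2$p_value, ref2$p.value, tolerance = 1e-10)
  expect_error(rank_test(numeric(0), 1), "non-empty")
})

test_that("precocious bolting: exact linear percentages give R-squared 1", {
  plants <- do.call(rbind, lapply(1:4, function(i) {
    n_bolt <- c(8, 6, 4, 2)[i]
    data.frame(genotype = paste0("g", i),
               bolted_before_winter = rep(c(TRUE, FALSE),
                                          c(n_bolt, 10 - n_bolt)),
               autumn_flc = c(1, 2, 3, 4)[i])
  }))
  res <- precocious_bolting_model(plants)
  expect_equal(res$r_squared, 1, tolerance = 1e-12)
  expect_lt(res$glm_slope, 0)
  expect_false(res$separation)
})

test_that("an all-or-nothing bolting response is flagged as inestimable", {
  plants <- data.frame(genotype = rep(c("a", "b", "c"), each = 5),
                       bolted_before_winter = FALSE,
                       autumn_flc = rep(c(1, 2, 3), each = 5))
  res <- precocious_bolting_model(plants)
  expect_true(res$separation)
  expect_true(is.null(res$glm_fit))
})

test_that("perfectly separated genotypes are flagged without crashing", {
  plants <- data.frame(genotype = rep(c("a", "b", "c", "d"), each = 20),
                       bolted_before_winter = rep(c(TRUE, FALSE),
                                                  each = 40),
                       autumn_flc = rep(c(0.1, 0.2, 5, 6), each = 20))
  res <- precocious_bolting_model(plants)
  expect_true(res$separation)
  expect_true(!is.null(res$glm_fit))
})

test_that("silique models recover an exact linear construction", {
  set.seed(71)
  s <- data.frame(genotype = paste0("g", 1:8),
                  postvern_m = c(20, 25, 30, 35, 40, 45, 50, 55),
                  pct_survival = c(60, 55, 70, 45, 65, 50, 40, 75))
  s$total_siliques <- 500 - 5 * s$postvern_m + 10 * s$pct_survival
  s$mean_rosette_branches <- 12 - 0.1 * s$postvern_m
  s$mean_siliques_survivors <- 30 + 8 * s$mean_rosette_branches
  res <- silique_models(s)
  expect_equal(unname(coef(res$total_model)[-1]), c(-5, 10),
               tolerance = 1e-8)
  expect_equal(res$total_adj_r_squared, 1, tolerance = 1e-8)
  expect_equal(unname(coef(res$survivors_vs_branches)[2]), 8,
               tolerance = 1e-8)
  expect_equal(unname(coef(res$branches_vs_postvern)[2]), -0.1,
               tolerance = 1e-8)
})

test_that("adjusted R-squared matches its closed form and lm's value", {
  set.seed(73)
  s <- data.frame(genotype = paste0("g", 1:10),
                  postvern_m = runif(10, 20, 60),
                  pct_survival = runif(10, 30, 80))
  s$total_siliques <- 400 - 3 * s$postvern_m + 6 * s$pct_survival +
    rnorm(10, 0, 50)
  s$mean_rosette_branches <- runif(10, 2, 10)
  s$mean_siliques_survivors <- runif(10, 40, 120)
  res <- silique_models(s)
  n <- 10; p <- 2
  closed <- 1 - (1 - res$total_r_squared) * (n - 1) / (n - p - 1)
  expect_equal(res$total_adj_r_squared, closed, tolerance = 1e-12)
  expect_equal(res$total_adj_r_squared,
               summary(res$total_model)$adj.r.squared, tolerance = 1e-12)
  expect_lte(res$total_adj_r_squared, res$total_r_squared)
})

test_that("permuted predictors carry little explanatory power", {
  set.seed(79)
  r2s <- replicate(500, {
    s <- data.frame(genotype = paste0("g", 1:10),
                    postvern_m = runif(10, 20, 60),
                    pct_survival = runif(10, 30, 80),
                    total_siliques = sample(rnorm(10, 500, 100)))
    summary(lm(total_siliques ~ postvern_m + pct_survival, s))$r.squared
  })
  expect_lt(mean(r2s), 0.3)  # two random predictors, n = 10
})

test_that("collinear predictors trigger a condition-number warning", {
  s <- data.frame(genotype = paste0("g", 1:6),
                  postvern_m = c(20, 25, 30, 35, 40, 45))
  s$pct_survival <- s$postvern_m * 2 + 1e-9
  s$total_siliques <- rnorm(6, 300, 10)
  s$mean_rosette_branches <- runif(6, 2, 8)
  s$mean_siliques_survivors <- runif(6, 50, 100)
  expect_warning(res <- silique_models(s), "condition number")
  expect_equal(nrow(res$reduction_steps), 0)
})

test_that("backward elimination drops non-significant terms with a log", {
  set.seed(83)
  s <- data.frame(genotype = paste0("g", 1:12),
                  postvern_m = runif(12, 20, 60),
                  pct_survival = runif(12, 30, 80))
  s$total_siliques <- 100 + 8 * s$pct_survival + rnorm(12, 0, 20)
  s$mean_rosette_branches <- runif(12, 2, 8)
  s$mean_siliques_survivors <- runif(12, 50, 100)
  res <- silique_models(s)
  expect_true("postvern_m" %in% res$reduction_steps$dropped)
  expect_false("postvern_m" %in% names(coef(res$reduced_model)))
})

test_that("the plant-level Poisson GLM recovers generating coefficients", {
  set.seed(89)
  branches <- rpois(300, 5)
  plants <- data.frame(survived = TRUE, rosette_branches = branches,
                       siliques = rpois(300, exp(1 + 0.1 * branches)))
  s <- data.frame(genotype = paste0("g", 1:4),
                  postvern_m = c(20, 30, 40, 50),
                  pct_survival = c(50, 65, 60, 80),
                  total_siliques = c(300, 420, 490, 610),
                  mean_rosette_branches = c(4, 5, 6, 7),
                  mean_siliques_survivors = c(60, 70, 80, 90))
  res <- silique_models(s, plants = plants)
  cf <- coef(summary(res$poisson_fit))
  expect_lt(abs(cf[1, 1] - 1), 3 * cf[1, 2])
  expect_lt(abs(cf[2, 1] - 0.1), 3 * cf[2, 2])
})

test_that("genotype summaries aggregate plant records faithfully", {
  plants <- data.frame(genotype = rep(c("a", "b"), each = 4),
                       bolted_before_winter = c(TRUE, TRUE, FALSE, FALSE,
                                                FALSE, FALSE, FALSE, TRUE),
                       survived = c(TRUE, FALSE, TRUE, TRUE,
                                    TRUE, TRUE, FALSE, FALSE),
                       rosette_branches = c(3, 0, 5, 4, 6, 7, 2, 1),
                       siliques = c(80, 0, 120, 100, 150, 130, 0, 0),
                       autumn_flc = rep(c(1.5, 3.2), each = 4))
  s <- fitness_summaries(plants, postvern = c(a = 30, b = 45))
  expect_equal(s$pct_bolted_before_winter, c(50, 25))
  expect_equal(s$pct_survival, c(75, 50))
  expect_equal(s$mean_siliques_survivors, c(100, 140))
  expect_equal(s$total_siliques, c(300, 280))
  expect_equal(s$postvern_m, c(30, 45))
  bad <- plants; bad$siliques[2] <- 10
  expect_error(fitness_summaries(bad), "0 siliques")
})
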