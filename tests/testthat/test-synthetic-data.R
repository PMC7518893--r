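test_that("zero-noise expression equals the piecewise trajectory, with floor", {
  cfg <- simulation_config(list(ref_genotype()),
                           timepoints = c(20, 30, 40, 50, 60),
                           breakpoint_day = 45, n_replicates = 3,
                           noise_sd_log = 0, block_sd_log = 0, floor = 0)
  sim <- simulate_expression(cfg)
  flc <- sim$expression[sim$expression$gene == "FLC_spliced", ]
  expected <- c(`20` = 6, `30` = 4, `40` = 2, `50` = 0, `60` = 0)
  for (d in names(expected)) {
    vals <- flc$value_au[flc$day == as.numeric(d)]
    expect_equal(vals, rep(expected[[d]], 3), tolerance = 1e-12)
  }
})

test_that("the noiseless mean is continuous at the breakpoint", {
  for (model in c("linear", "exponential")) {
    left <- flc_trajectory(45, 10, 0.2, 0.3, 45, model, floor = 0)
    right <- flc_trajectory(45 + 1e-9, 10, 0.2, 0.3, 45, model, floor = 0)
    expect_equal(left, right, tolerance = 1e-6)
  }
})

test_that("identical config and seed give identical outputs", {
  cfg <- two_phase_config(noise_sd_log = 0.2, block_sd_log = 0.1,
                          transfer_days = c(27, 55, 69), seed = 42)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical_tables(a$expression, b$expression)
  expect_identical_tables(simulate_transfers(cfg), simulate_transfers(cfg))
  expect_identical_tables(simulate_fitness(cfg), simulate_fitness(cfg))
})

test_that("two-phase simulation rejects a breakpoint outside the sampled range", {
  expect_error(
    simulation_config(list(ref_genotype()), timepoints = c(20, 30, 40),
                      breakpoint_day = 90),
    "breakpoint_day.*within the sampled timepoint range")
})

test_that("transfer bolting follows the post-vern model and censors at follow-up", {
  g <- genotype_params("g1", 10, 0.2, 0.3, postvern_m = 36.5,
                       postvern_c = 20)
  cfg <- simulation_config(list(g), timepoints = c(10, 20, 30, 50, 60),
                           breakpoint_day = 40, noise_sd_log = 0,
                           block_sd_log = 0, transfer_days = 40,
                           bolting_noise_sd = 0, floor = 0)
  # E(40) = 10 - 0.2*40 = 2 -> 36.5*2 + 20 = 93 days
  tr <- simulate_transfers(cfg)
  expect_equal(unique(tr$days_to_bolting), 93, tolerance = 1e-12)
  expect_false(any(tr$dnf))

  g2 <- genotype_params("slow", 10, 0.2, 0.3, postvern_m = 113,
                        postvern_c = 20)
  cfg2 <- simulation_config(list(g2), timepoints = c(10, 20, 35, 50, 60),
                            breakpoint_day = 40, noise_sd_log = 0,
                            block_sd_log = 0, transfer_days = 35,
                            bolting_noise_sd = 0, max_followup_days = 205,
                            floor = 0)
  # E(35) = 3 -> 113*3 + 20 = 359 > 205 -> censored DNF
  tr2 <- simulate_transfers(cfg2)
  expect_true(all(tr2$dnf))
  expect_true(all(is.na(tr2$days_to_bolting)))
})

test_that("negative bolting noise is rejected", {
  expect_error(
    simulation_config(list(ref_genotype()), timepoints = c(20, 30, 50, 60),
                      breakpoint_day = 40, transfer_days = 30,
                      bolting_noise_sd = -1),
    "bolting_noise_sd")
})

test_that("replicate log-variance converges to noise_sd^2 + block_sd^2", {
  cfg <- simulation_config(list(ref_genotype(S = 10, r1 = 0, r2 = 0)),
                           timepoints = c(0, 100), breakpoint_day = 50,
                           n_replicates = 10000, n_blocks = 400,
                           noise_sd_log = 0.3, block_sd_log = 0.2,
                           two_phase = FALSE, seed = 7)
  sim <- simulate_expression(cfg)
  flc <- sim$expression[sim$expression$gene == "FLC_spliced" &
                          sim$expression$day == 0, ]
  v <- var(log(flc$value_au))
  expect_lt(abs(v - (0.3^2 + 0.2^2)) / (0.3^2 + 0.2^2), 0.05)
})

test_that("zero precocity slope gives FLC-independent bolting probabilities", {
  gs <- list(genotype_params("low", 1, 0.01, 0.01,
                             precocity_logit_slope = 0),
             genotype_params("high", 30, 0.01, 0.01,
                             precocity_logit_slope = 0))
  cfg <- simulation_config(gs, timepoints = c(10, 20, 40, 60),
                           breakpoint_day = 30, n_fitness_plants = 4000,
                           seed = 11)
  fit <- simulate_fitness(cfg)
  rates <- tapply(fit$bolted_before_winter, fit$genotype, mean)
  expect_lt(abs(rates[["low"]] - rates[["high"]]), 0.04)
})

test_that("silique counts match the closed-form Poisson mean", {
  g <- genotype_params("g", 5, 0.05, 0.05, postvern_m = 20,
                       survival_penalty_logit = 0, branch_base = 8,
                       branch_postvern_slope = 0.1)
  cfg <- simulation_config(list(g), timepoints = c(10, 20, 40, 60),
                           breakpoint_day = 30, n_fitness_plants = 10000,
                           survival_logit_base = 20,  # all survive
                           branch_noise_sd = 0, silique_alpha = 3,
                           silique_beta = 0.15, seed = 5)
  fit <- simulate_fitness(cfg)
  expect_true(all(fit$survived))
  branches <- round(8 - 0.1 * 20)  # deterministic
  lambda <- exp(3 + 0.15 * branches)
  expect_lt(abs(mean(fit$siliques) - lambda), 4 * sqrt(lambda / 10000))
})

test_that("non-survivors set no siliques and counts are non-negative", {
  cfg <- two_phase_config(seed = 3)
  fit <- simulate_fitness(cfg)
  expect_true(all(fit$siliques[!fit$survived] == 0))
  expect_true(all(fit$rosette_branches >= 0))
  expect_true(all(fit$siliques >= 0))
})
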