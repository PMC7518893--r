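#' Per-genotype ground-truth parameters for simulation
#'
#' Bundles the quantities that characterise one genotype in a simulated field
#' experiment: the FLC expression trajectory (starting level and the two
#' phase-specific decline rates), the post-vernalization flowering
#' relationship (`days to bolting = m * FLC + c`), and the fitness-model
#' parameters (precocious-bolting sensitivity, overwinter survival penalty
#' for bolted plants, and branching).
#'
#' Slowly vernalizing (SV-like) genotypes may have slower rates in both
#' phases; no ordering between `rate_vindep` and `rate_vdep` is imposed.
#'
#' @param genotype_id Genotype label.
#' @param starting_level FLC abundance (a.u.) at sowing; must be > 0.
#' @param rate_vindep VIN3-independent decline rate (a.u./day in linear mode,
#'   /day in exponential mode); magnitude, >= 0.
#' @param rate_vdep VIN3-dependent decline rate; magnitude, >= 0.
#' @param postvern_m Post-vernalization slope, days to bolting per a.u. of
#'   FLC at transfer (>= 0).
#' @param postvern_c Post-vernalization intercept, days (>= 0): bolting delay
#'   not mediated by FLC.
#' @param precocity_logit_slope Logit decrease in the probability of bolting
#'   before winter per a.u. of autumn FLC.
#' @param survival_penalty_logit Logit reduction in overwinter survival for
#'   plants that bolted before winter.
#' @param branch_base Baseline rosette branch count.
#' @param branch_postvern_slope Branches lost per unit of `postvern_m`.
#' @return An object of class `genotype_params`.
#' @export
genotype_params <- function(genotype_id, starting_level, rate_vindep,
                            rate_vdep, postvern_m = 35, postvern_c = 20,
                            precocity_logit_slope = 1.5,
                            survival_penalty_logit = 1.03,
                            branch_base = 10, branch_postvern_slope = 0.15) {
  if (!is.character(genotype_id) || length(genotype_id) != 1)
    stopf("`genotype_id` must be a single label")
  assert_number(starting_level, "starting_level", lower = 0,
                strict_lower = TRUE)
  assert_number(rate_vindep, "rate_vindep", lower = 0)
  assert_number(rate_vdep, "rate_vdep", lower = 0)
  assert_number(postvern_m, "postvern_m", lower = 0)
  assert_number(postvern_c, "postvern_c", lower = 0)
  assert_number(precocity_logit_slope, "precocity_logit_slope")
  assert_number(survival_penalty_logit, "survival_penalty_logit")
  assert_number(branch_base, "branch_base", lower = 0)
  assert_number(branch_postvern_slope, "branch_postvern_slope")
  structure(list(genotype_id = genotype_id,
                 starting_level = starting_level,
                 rate_vindep = rate_vindep, rate_vdep = rate_vdep,
                 postvern_m = postvern_m, postvern_c = postvern_c,
                 precocity_logit_slope = precocity_logit_slope,
                 survival_penalty_logit = survival_penalty_logit,
                 branch_base = branch_base,
                 branch_postvern_slope = branch_postvern_slope),
            class = "genotype_params")
}

#' Configuration of a simulated field experiment
#'
#' Defines the design of a synthetic field experiment: which genotypes are
#' grown, when material is sampled, when VIN3 induction switches the FLC
#' shutdown from its VIN3-independent to its VIN3-dependent phase, the
#' replication and noise structure, the warm-transfer schedule, and the
#' autumn census used by the fitness stage.
#'
#' Defaults mirror a typical field season: 6 replicate samples per
#' genotype and timepoint in 3 randomised blocks, 12 plants per warm
#' transfer, 36 plants per genotype scored for fitness, and a 205-day
#' post-transfer follow-up after which unflowered plants are censored
#' (recorded as DNF, "did not flower").
#'
#' @param genotypes List of [genotype_params()] objects.
#' @param timepoints Strictly increasing days-after-sowing at which
#'   expression is sampled.
#' @param breakpoint_day Site-level day of substantial VIN3 induction.
#' @param n_replicates Replicate samples per genotype x timepoint.
#' @param n_blocks Number of randomised blocks; replicates are assigned to
#'   blocks cyclically and block effects are shared across genotypes.
#' @param noise_sd_log SD of multiplicative log-normal replicate noise.
#' @param block_sd_log SD of log-scale block effects.
#' @param transfer_days Days-after-sowing of transfers to warm, inductive
#'   conditions (must lie within the sampled range); `NULL` disables the
#'   transfer experiment.
#' @param n_transfer_plants Plants per genotype per transfer.
#' @param bolting_noise_sd SD (days) of bolting-time noise.
#' @param max_followup_days Censoring horizon: plants not bolting within this
#'   many days are recorded as DNF.
#' @param autumn_census_day Day of the autumn bolting census used by the
#'   fitness stage; default is the last timepoint at or before
#'   `breakpoint_day`.
#' @param n_fitness_plants Plants per genotype scored for fitness.
#' @param precocity_logit_intercept Logit of the probability of bolting
#'   before winter at zero autumn FLC.
#' @param survival_logit_base Logit of overwinter survival for plants that
#'   did not bolt before winter (default `qlogis(0.67)`).
#' @param branch_noise_sd SD of branch-count noise (before flooring at 0).
#' @param cauline_mean Poisson mean of cauline branch counts.
#' @param silique_alpha,silique_beta Silique counts of survivors are Poisson
#'   with `log(lambda) = silique_alpha + silique_beta * rosette_branches`.
#' @param vin3_baseline,vin3_induced Mean VIN3 level (a.u.) before and after
#'   `breakpoint_day`.
#' @param decline_model `"linear"` (a.u./day slopes) or `"exponential"`
#'   (log-linear decline).
#' @param two_phase Whether the trajectory has distinct phase rates around
#'   the breakpoint. When `TRUE`, `breakpoint_day` must lie within the
#'   sampled range.
#' @param floor Lower truncation of expression (a.u.); keeps values
#'   non-negative and positive in exponential mode.
#' @param site,year Labels copied into the output tables.
#' @param seed Integer seed; identical configurations give byte-identical
#'   output. [simulate_transfers()] and [simulate_fitness()] use streams
#'   derived from `seed + 1` and `seed + 2`.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(genotypes, timepoints, breakpoint_day,
                              n_replicates = 6, n_blocks = 3,
                              noise_sd_log = 0.2, block_sd_log = 0.1,
                              transfer_days = NULL, n_transfer_plants = 12,
                              bolting_noise_sd = 5, max_followup_days = 205,
                              autumn_census_day = NULL, n_fitness_plants = 36,
                              precocity_logit_intercept = 2,
                              survival_logit_base = qlogis(0.67),
                              branch_noise_sd = 1, cauline_mean = 2,
                              silique_alpha = 3, silique_beta = 0.15,
                              vin3_baseline = 0.05, vin3_induced = 1.5,
                              decline_model = c("linear", "exponential"),
                              two_phase = TRUE, floor = 0.01,
                              site = "Norwich", year = 2016, seed = 1L) {
  decline_model <- match.arg(decline_model)
  if (inherits(genotypes, "genotype_params")) genotypes <- list(genotypes)
  if (!length(genotypes) || !all(vapply(genotypes, inherits, logical(1),
                                        "genotype_params")))
    stopf("`genotypes` must be a list of genotype_params objects")
  ids <- vapply(genotypes, `[[`, character(1), "genotype_id")
  if (anyDuplicated(ids)) stopf("duplicate genotype_id in `genotypes`")
  if (length(timepoints) < 2 || any(diff(timepoints) <= 0))
    stopf("`timepoints` must be strictly increasing with >= 2 entries")
  assert_number(breakpoint_day, "breakpoint_day")
  if (two_phase &&
      (breakpoint_day < min(timepoints) || breakpoint_day > max(timepoints)))
    stopf(paste0("two-phase simulation requires `breakpoint_day` within the ",
                 "sampled timepoint range [%g, %g], got %g"),
          min(timepoints), max(timepoints), breakpoint_day)
  if (two_phase && (sum(timepoints <= breakpoint_day) < 2 ||
                    sum(timepoints > breakpoint_day) < 2))
    warnf("fewer than 2 timepoints on one side of the breakpoint; two-phase fitting will not be possible")
  assert_number(n_replicates, "n_replicates", lower = 1)
  assert_number(n_blocks, "n_blocks", lower = 1)
  assert_number(noise_sd_log, "noise_sd_log", lower = 0)
  assert_number(block_sd_log, "block_sd_log", lower = 0)
  if (!is.null(transfer_days)) {
    if (any(transfer_days < min(timepoints)) ||
        any(transfer_days > max(timepoints)))
      stopf("`transfer_days` must lie within the sampled timepoint range")
  }
  if (bolting_noise_sd < 0) stopf("`bolting_noise_sd` must be >= 0")
  assert_number(max_followup_days, "max_followup_days", lower = 1)
  assert_number(floor, "floor", lower = 0)
  if (is.null(autumn_census_day)) {
    pre <- timepoints[timepoints <= breakpoint_day]
    autumn_census_day <- if (length(pre)) max(pre) else timepoints[1]
  }
  structure(list(genotypes = genotypes, timepoints = timepoints,
                 breakpoint_day = breakpoint_day,
                 n_replicates = as.integer(n_replicates),
                 n_blocks = as.integer(n_blocks),
                 noise_sd_log = noise_sd_log, block_sd_log = block_sd_log,
                 transfer_days = transfer_days,
                 n_transfer_plants = as.integer(n_transfer_plants),
                 bolting_noise_sd = bolting_noise_sd,
                 max_followup_days = max_followup_days,
                 autumn_census_day = autumn_census_day,
                 n_fitness_plants = as.integer(n_fitness_plants),
                 precocity_logit_intercept = precocity_logit_intercept,
                 survival_logit_base = survival_logit_base,
                 branch_noise_sd = branch_noise_sd,
                 cauline_mean = cauline_mean,
                 silique_alpha = silique_alpha, silique_beta = silique_beta,
                 vin3_baseline = vin3_baseline, vin3_induced = vin3_induced,
                 decline_model = decline_model, two_phase = two_phase,
                 floor = floor, site = site, year = year,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Noiseless piecewise FLC trajectory
#'
#' Mean FLC abundance at day `t` for a two-phase shutdown: rate `r1` up to
#' the breakpoint, rate `r2` after it, continuous at the breakpoint and
#' truncated below at `floor`. In linear mode `E(t) = S - r1 t` then
#' `E(T*) - r2 (t - T*)`; in exponential mode the decline is log-linear,
#' `E(t) = S exp(-r1 t)` then `E(T*) exp(-r2 (t - T*))`.
#'
#' @param t Days after sowing (vectorised).
#' @param starting_level FLC at day 0 (a.u.).
#' @param rate_vindep,rate_vdep Decline-rate magnitudes for the two phases.
#' @param breakpoint_day Day of VIN3 induction.
#' @param model `"linear"` or `"exponential"`.
#' @param floor Lower truncation (a.u.).
#' @return Numeric vector of mean expression values.
#' @export
flc_trajectory <- function(t, starting_level, rate_vindep, rate_vdep,
                           breakpoint_day, model = c("linear", "exponential"),
                           floor = 0.01) {
  model <- match.arg(model)
  if (model == "linear") {
    e_bp <- starting_level - rate_vindep * breakpoint_day
    out <- ifelse(t <= breakpoint_day,
                  starting_level - rate_vindep * t,
                  e_bp - rate_vdep * (t - breakpoint_day))
  } else {
    e_bp <- starting_level * exp(-rate_vindep * breakpoint_day)
    out <- ifelse(t <= breakpoint_day,
                  starting_level * exp(-rate_vindep * t),
                  e_bp * exp(-rate_vdep * (t - breakpoint_day)))
  }
  pmax(out, floor)
}

truth_table <- function(config) {
  g <- config$genotypes
  data.frame(genotype = vapply(g, `[[`, character(1), "genotype_id"),
             starting_level = vapply(g, `[[`, numeric(1), "starting_level"),
             rate_vindep = vapply(g, `[[`, numeric(1), "rate_vindep"),
             rate_vdep = vapply(g, `[[`, numeric(1), "rate_vdep"),
             postvern_m = vapply(g, `[[`, numeric(1), "postvern_m"),
             postvern_c = vapply(g, `[[`, numeric(1), "postvern_c"),
             breakpoint_day = config$breakpoint_day,
             stringsAsFactors = FALSE)
}

#' Simulate normalized expression time courses
#'
#' Generates replicate-level normalized FLC and VIN3 expression for every
#' genotype and timepoint in `config`. The FLC mean follows the piecewise
#' trajectory of [flc_trajectory()]; VIN3 sits at `vin3_baseline` until the
#' breakpoint day and at `vin3_induced` after it. Replicate values are the
#' mean times `exp(N(0, noise_sd_log^2))` times a log-normal block effect
#' shared across genotypes within a block. Output is deterministic given the
#' configuration (including its seed).
#'
#' @param config A [simulation_config()].
#' @return A list with components `expression` (data frame with columns
#'   genotype, site, year, day, block, replicate, gene, value_au) and
#'   `truth` (one row per genotype with the true parameters plus the
#'   site-level breakpoint day).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  truth <- truth_table(config)
  grid <- expand.grid(replicate = seq_len(config$n_replicates),
                      day = config$timepoints,
                      genotype = truth$genotype,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$block <- ((grid$replicate - 1L) %% config$n_blocks) + 1L
  idx <- match(grid$genotype, truth$genotype)
  mean_flc <- flc_trajectory(grid$day, truth$starting_level[idx],
                             truth$rate_vindep[idx], truth$rate_vdep[idx],
                             config$breakpoint_day, config$decline_model,
                             config$floor)
  mean_vin3 <- ifelse(grid$day <= config$breakpoint_day,
                      config$vin3_baseline, config$vin3_induced)
  n <- nrow(grid)
  withr::with_seed(config$seed, {
    block_eff <- rnorm(config$n_blocks, 0, config$block_sd_log)
    noise_flc <- rnorm(n, 0, config$noise_sd_log)
    noise_vin3 <- rnorm(n, 0, config$noise_sd_log)
  })
  be <- block_eff[grid$block]
  expr <- rbind(
    data.frame(genotype = grid$genotype, site = config$site,
               year = config$year, day = grid$day, block = grid$block,
               replicate = grid$replicate, gene = "FLC_spliced",
               value_au = mean_flc * exp(noise_flc + be),
               stringsAsFactors = FALSE),
    data.frame(genotype = grid$genotype, site = config$site,
               year = config$year, day = grid$day, block = grid$block,
               replicate = grid$replicate, gene = "VIN3",
               value_au = mean_vin3 * exp(noise_vin3 + be),
               stringsAsFactors = FALSE))
  rownames(expr) <- NULL
  list(expression = expr, truth = truth)
}

#' Simulate warm-transfer bolting times
#'
#' For each genotype and transfer day, generates bolting times of plants
#' moved from the field to warm, inductive conditions according to the
#' post-vernalization model `days to bolting = m * FLC(t_transfer) + c +
#' N(0, bolting_noise_sd^2)`, floored at 1 day. Plants whose bolting time
#' exceeds `max_followup_days` are right-censored and recorded as DNF
#' ("did not flower"). The FLC covariate is the true mean trajectory at the
#' transfer day (column `flc_at_transfer`); when `expression` is supplied,
#' the measured replicate mean at matching sampled days is attached as
#' `flc_measured`.
#'
#' Uses the RNG stream derived from `config$seed + 1`.
#'
#' @param config A [simulation_config()] with non-`NULL` `transfer_days`.
#' @param expression Optional expression table from [simulate_expression()].
#' @return Data frame with columns genotype, site, year, transfer_day,
#'   plant, flc_at_transfer, flc_measured, days_to_bolting (`NA` when
#'   censored), dnf (logical).
#' @export
simulate_transfers <- function(config, expression = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(config$transfer_days))
    stopf("`config$transfer_days` is NULL: no transfer experiment to simulate")
  if (config$bolting_noise_sd < 0)
    stopf("`bolting_noise_sd` must be >= 0")
  truth <- truth_table(config)
  grid <- expand.grid(plant = seq_len(config$n_transfer_plants),
                      transfer_day = config$transfer_days,
                      genotype = truth$genotype,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- match(grid$genotype, truth$genotype)
  flc <- flc_trajectory(grid$transfer_day, truth$starting_level[idx],
                        truth$rate_vindep[idx], truth$rate_vdep[idx],
                        config$breakpoint_day, config$decline_model,
                        config$floor)
  withr::with_seed(config$seed + 1L, {
    noise <- rnorm(nrow(grid), 0, config$bolting_noise_sd)
  })
  bolt <- pmax(truth$postvern_m[idx] * flc + truth$postvern_c[idx] + noise, 1)
  dnf <- bolt > config$max_followup_days
  flc_measured <- rep(NA_real_, nrow(grid))
  if (!is.null(expression)) {
    fl <- expression[expression$gene == "FLC_spliced", , drop = FALSE]
    means <- stats::aggregate(value_au ~ genotype + day, data = fl, FUN = mean)
    m <- match(paste(grid$genotype, grid$transfer_day),
               paste(means$genotype, means$day))
    flc_measured <- means$value_au[m]
  }
  data.frame(genotype = grid$genotype, site = config$site, year = config$year,
             transfer_day = grid$transfer_day, plant = grid$plant,
             flc_at_transfer = flc, flc_measured = flc_measured,
             days_to_bolting = ifelse(dnf, NA_real_, bolt), dnf = dnf,
             stringsAsFactors = FALSE)
}

#' Simulate overwinter fitness outcomes
#'
#' For each genotype, generates `n_fitness_plants` plants with: precocious
#' bolting before winter, Bernoulli with
#' `logit(p) = precocity_logit_intercept - precocity_logit_slope * FLC_autumn`;
#' overwinter survival, Bernoulli with
#' `logit(p) = survival_logit_base - survival_penalty_logit * bolted`;
#' rosette branch counts, `round(branch_base - branch_postvern_slope * m +
#' N(0, branch_noise_sd^2))` floored at 0; cauline branches Poisson; and
#' silique counts, Poisson with
#' `log(lambda) = silique_alpha + silique_beta * rosette_branches` for
#' survivors and 0 otherwise. The autumn FLC covariate is the true mean
#' trajectory at `config$autumn_census_day`.
#'
#' Uses the RNG stream derived from `config$seed + 2`.
#'
#' @param config A [simulation_config()].
#' @param expression Optional expression table (attaches the measured
#'   replicate-mean autumn FLC as `autumn_flc_measured`).
#' @return Data frame with one row per plant: genotype, site, year, plant,
#'   autumn_flc, bolted_before_winter, survived, rosette_branches,
#'   cauline_branches, siliques.
#' @export
simulate_fitness <- function(config, expression = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  truth <- truth_table(config)
  g <- config$genotypes
  slope <- vapply(g, `[[`, numeric(1), "precocity_logit_slope")
  penalty <- vapply(g, `[[`, numeric(1), "survival_penalty_logit")
  bbase <- vapply(g, `[[`, numeric(1), "branch_base")
  bslope <- vapply(g, `[[`, numeric(1), "branch_postvern_slope")
  grid <- expand.grid(plant = seq_len(config$n_fitness_plants),
                      genotype = truth$genotype,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- match(grid$genotype, truth$genotype)
  e_aut <- flc_trajectory(rep(config$autumn_census_day, nrow(truth)),
                          truth$starting_level, truth$rate_vindep,
                          truth$rate_vdep, config$breakpoint_day,
                          config$decline_model, config$floor)
  p_bolt <- plogis(config$precocity_logit_intercept - slope[idx] * e_aut[idx])
  n <- nrow(grid)
  withr::with_seed(config$seed + 2L, {
    bolted <- rbinom(n, 1, p_bolt)
    p_surv <- plogis(config$survival_logit_base - penalty[idx] * bolted)
    survived <- rbinom(n, 1, p_surv)
    branches <- pmax(round(bbase[idx] -
                             bslope[idx] * truth$postvern_m[idx] +
                             rnorm(n, 0, config$branch_noise_sd)), 0)
    cauline <- rpois(n, config$cauline_mean)
    siliques <- ifelse(survived == 1,
                       rpois(n, exp(config$silique_alpha +
                                      config$silique_beta * branches)), 0L)
  })
  out <- data.frame(genotype = grid$genotype, site = config$site,
                    year = config$year, plant = grid$plant,
                    autumn_flc = e_aut[idx],
                    bolted_before_winter = bolted == 1,
                    survived = survived == 1,
                    rosette_branches = as.integer(branches),
                    cauline_branches = as.integer(cauline),
                    siliques = as.integer(siliques),
                    stringsAsFactors = FALSE)
  if (!is.null(expression)) {
    fl <- expression[expression$gene == "FLC_spliced" &
                       expression$day == config$autumn_census_day, ,
                     drop = FALSE]
    if (nrow(fl)) {
      means <- stats::aggregate(value_au ~ genotype, data = fl, FUN = mean)
      out$autumn_flc_measured <- means$value_au[match(out$genotype,
                                                      means$genotype)]
    }
  }
  out
}
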