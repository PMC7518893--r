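#' Summarise plant-level fitness records per genotype
#'
#' @param plants Plant-level data frame with columns `genotype`,
#'   `bolted_before_winter`, `survived`, `rosette_branches`, `siliques`,
#'   optionally `autumn_flc`.
#' @param postvern Optional named numeric vector of post-vern `m` values
#'   per genotype (joined into the summary as `postvern_m`).
#' @return Data frame with one row per genotype: `pct_bolted_before_winter`,
#'   `pct_survival`, `mean_siliques_survivors`, `mean_rosette_branches`
#'   (survivors), `total_siliques`, `n_plants`, plus `autumn_flc` and
#'   `postvern_m` when available.
#' @export
fitness_summaries <- function(plants, postvern = NULL) {
  assert_columns(plants, c("genotype", "bolted_before_winter", "survived",
                           "rosette_branches", "siliques"),
                 "fitness table")
  if (any(plants$siliques[!plants$survived] != 0))
    stopf("non-survivors must have 0 siliques")
  if (any(plants$rosette_branches < 0 | plants$siliques < 0))
    stopf("counts must be >= 0")
  gs <- unique(plants$genotype)
  out <- lapply(gs, function(g) {
    sub <- plants[plants$genotype == g, , drop = FALSE]
    surv <- sub[sub$survived, , drop = FALSE]
    data.frame(
      genotype = g,
      pct_bolted_before_winter = 100 * mean(sub$bolted_before_winter),
      pct_survival = 100 * mean(sub$survived),
      mean_siliques_survivors = if (nrow(surv)) mean(surv$siliques)
      else NA_real_,
      mean_rosette_branches = if (nrow(surv)) mean(surv$rosette_branches)
      else NA_real_,
      total_siliques = sum(sub$siliques),
      n_plants = nrow(sub),
      autumn_flc = if ("autumn_flc" %in% names(sub))
        mean(sub$autumn_flc) else NA_real_,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (!is.null(postvern))
    res$postvern_m <- unname(postvern[res$genotype])
  rownames(res) <- NULL
  res
}

#' Precocious-bolting models
#'
#' Two complementary summaries of the relationship between autumn FLC and
#' bolting before winter: (i) a plant-level binomial GLM with logit link of
#' the bolting indicator on genotype autumn FLC, and (ii) the genotype-level
#' linear regression of the percentage of plants bolting before winter on
#' autumn FLC, reported as R-squared. Perfect separation (or a constant
#' response) is flagged rather than raised.
#'
#' @param plants Plant-level data frame with `genotype` and
#'   `bolted_before_winter`.
#' @param autumn_flc Named numeric vector of autumn FLC per genotype, or
#'   `NULL` to use an `autumn_flc` column of `plants`.
#' @return An object of class `precocious_bolting_model`: list with
#'   `glm_fit`, `glm_slope`, `glm_slope_se`, `glm_p`, `separation`,
#'   `genotype_table` (genotype, pct_bolted, autumn_flc), `lm_fit`,
#'   `r_squared`, `lm_p`.
#' @export
precocious_bolting_model <- function(plants, autumn_flc = NULL) {
  assert_columns(plants, c("genotype", "bolted_before_winter"),
                 "fitness table")
  if (is.null(autumn_flc)) {
    assert_columns(plants, "autumn_flc", "fitness table")
    autumn_flc <- vapply(split(plants$autumn_flc, plants$genotype), mean,
                         numeric(1))
  }
  gs <- unique(plants$genotype)
  if (length(gs) < 3)
    stopf("need >= 3 genotypes with bolting counts and FLC")
  if (!all(gs %in% names(autumn_flc)))
    stopf("autumn FLC missing for genotype(s): %s",
          paste(setdiff(gs, names(autumn_flc)), collapse = ", "))
  flc <- unname(autumn_flc[plants$genotype])
  y <- as.integer(plants$bolted_before_winter)
  separation <- FALSE
  glm_fit <- NULL
  glm_slope <- glm_slope_se <- glm_p <- NA_real_
  if (length(unique(y)) < 2) {
    separation <- TRUE
  } else {
    glm_fit <- withCallingHandlers(
      glm(y ~ flc, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                  conditionMessage(w))) {
          separation <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    sm <- summary(glm_fit)$coefficients
    glm_slope <- sm["flc", "Estimate"]
    glm_slope_se <- sm["flc", "Std. Error"]
    glm_p <- sm["flc", "Pr(>|z|)"]
  }
  gtab <- data.frame(
    genotype = gs,
    pct_bolted = vapply(gs, function(g)
      100 * mean(plants$bolted_before_winter[plants$genotype == g]),
      numeric(1)),
    autumn_flc = unname(autumn_flc[gs]),
    row.names = NULL, stringsAsFactors = FALSE)
  lm_fit <- lm(pct_bolted ~ autumn_flc, data = gtab)
  lsm <- suppressWarnings(summary(lm_fit))
  structure(list(glm_fit = glm_fit, glm_slope = glm_slope,
                 glm_slope_se = glm_slope_se, glm_p = glm_p,
                 separation = separation, genotype_table = gtab,
                 lm_fit = lm_fit, r_squared = lsm$r.squared,
                 lm_p = lsm$coefficients["autumn_flc", "Pr(>|t|)"]),
            class = "precocious_bolting_model")
}

#' Two-proportion test of overwinter survival
#'
#' Chi-square test of equal survival proportions between plants that bolted
#' before winter and plants that did not (the conventional reading of a
#' "binomial proportions test"); Fisher's exact test is available as an
#' option for small or extreme tables.
#'
#' @param bolted,not_bolted Each `c(successes, n)`: survivors and total
#'   plants in the arm.
#' @param correct Apply Yates' continuity correction (default `FALSE`).
#' @param method `"chisq"` or `"fisher"`.
#' @return List with `prop_bolted`, `prop_not_bolted`, `statistic` (`NA`
#'   for Fisher), `p_value`, `method`.
#' @export
survival_proportion_test <- function(bolted, not_bolted, correct = FALSE,
                                     method = c("chisq", "fisher")) {
  method <- match.arg(method)
  for (arm in list(bolted, not_bolted)) {
    if (length(arm) != 2 || arm[2] < 1 || arm[1] < 0 || arm[1] > arm[2])
      stopf("each arm must be c(successes, n) with n >= 1 and 0 <= successes <= n")
  }
  if (method == "chisq") {
    tst <- suppressWarnings(prop.test(c(bolted[1], not_bolted[1]),
                                      c(bolted[2], not_bolted[2]),
                                      correct = correct))
    statistic <- unname(tst$statistic)
    p <- tst$p.value
  } else {
    tab <- rbind(c(bolted[1], bolted[2] - bolted[1]),
                 c(not_bolted[1], not_bolted[2] - not_bolted[1]))
    tst <- stats::fisher.test(tab)
    statistic <- NA_real_
    p <- tst$p.value
  }
  list(prop_bolted = bolted[1] / bolted[2],
       prop_not_bolted = not_bolted[1] / not_bolted[2],
       statistic = statistic, p_value = p, method = method)
}

adj_r_squared <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

#' Genotype-level silique (fitness) models
#'
#' Fits the three genotype-level regressions linking fecundity to branching
#' and the post-vern statistic: (i) mean siliques of survivors on mean
#' rosette branches; (ii) mean rosette branches on post-vern `m`; and
#' (iii) total siliques on post-vern `m` plus percentage survival to seed
#' set, reporting the adjusted R-squared
#' `1 - (1 - R2)(n - 1)/(n - p - 1)`. Model (iii) is then reduced to a
#' minimal adequate model by backward elimination: the least significant
#' term is dropped while its p-value exceeds `reduce_alpha`, with every
#' step logged. Near-collinear predictors (condition number of the model
#' matrix above `kappa_max`) trigger a warning and disable the automatic
#' reduction. Optionally fits a plant-level Poisson GLM of silique counts
#' on rosette branches for survivors (the count-data choice when n is
#' large enough for a GLM, conventionally n > 10).
#'
#' @param summaries Genotype-level table from [fitness_summaries()] (needs
#'   `mean_siliques_survivors`, `mean_rosette_branches`, `postvern_m`,
#'   `pct_survival`, `total_siliques`).
#' @param plants Optional plant-level table for the Poisson GLM.
#' @param reduce_alpha Threshold for backward elimination (default 0.05).
#' @param kappa_max Condition-number limit (default 1e8).
#' @return An object of class `silique_models`: list with
#'   `survivors_vs_branches`, `branches_vs_postvern`, `total_model` (each
#'   an `lm`), `total_r_squared`, `total_adj_r_squared`, `reduction_steps`
#'   (data frame), `reduced_model`, and `poisson_fit` (or `NULL`).
#' @export
silique_models <- function(summaries, plants = NULL, reduce_alpha = 0.05,
                           kappa_max = 1e8) {
  assert_columns(summaries, c("genotype", "mean_siliques_survivors",
                              "mean_rosette_branches", "postvern_m",
                              "pct_survival", "total_siliques"),
                 "genotype fitness summary")
  s <- summaries[stats::complete.cases(
    summaries[, c("mean_siliques_survivors", "mean_rosette_branches",
                  "postvern_m", "pct_survival", "total_siliques")]), ,
    drop = FALSE]
  if (nrow(s) < 4)
    stopf("need >= 4 genotypes with complete data for the two-predictor model")
  m1 <- lm(mean_siliques_survivors ~ mean_rosette_branches, data = s)
  m2 <- lm(mean_rosette_branches ~ postvern_m, data = s)
  m3 <- lm(total_siliques ~ postvern_m + pct_survival, data = s)
  r2 <- suppressWarnings(summary(m3))$r.squared
  adj <- adj_r_squared(r2, nrow(s), 2)
  kp <- kappa(model.matrix(m3), exact = TRUE)
  steps <- data.frame(dropped = character(), p_dropped = numeric(),
                      remaining = character(), stringsAsFactors = FALSE)
  reduced <- m3
  if (kp > kappa_max) {
    warnf("model matrix condition number %.3g exceeds %.3g: predictors are near-collinear; skipping model reduction",
          kp, kappa_max)
  } else {
    repeat {
      ct <- suppressWarnings(summary(reduced))$coefficients
      terms <- setdiff(rownames(ct), "(Intercept)")
      if (length(terms) == 0) break
      pv <- ct[terms, "Pr(>|t|)"]
      worst <- terms[which.max(pv)]
      if (max(pv) <= reduce_alpha) break
      reduced <- update(reduced, as.formula(paste(". ~ . -", worst)))
      steps <- rbind(steps, data.frame(
        dropped = worst, p_dropped = max(pv),
        remaining = paste(setdiff(terms, worst), collapse = " + "),
        stringsAsFactors = FALSE))
    }
  }
  poisson_fit <- NULL
  if (!is.null(plants)) {
    assert_columns(plants, c("survived", "siliques", "rosette_branches"),
                   "plant-level fitness table")
    surv <- plants[plants$survived, , drop = FALSE]
    if (nrow(surv) > 10)
      poisson_fit <- glm(siliques ~ rosette_branches, data = surv,
                         family = poisson())
  }
  structure(list(survivors_vs_branches = m1, branches_vs_postvern = m2,
                 total_model = m3, total_r_squared = r2,
                 total_adj_r_squared = adj, condition_number = kp,
                 reduction_steps = steps, reduced_model = reduced,
                 poisson_fit = poisson_fit),
            class = "silique_models")
}

#' Mann-Whitney U rank test
#'
#' Two-sided Mann-Whitney U test with midrank tie handling. For combined
#' sample sizes up to `exact_limit` the null distribution of U is obtained
#' by full enumeration over all group assignments (valid with ties); larger
#' samples use the tie-corrected normal approximation with optional
#' continuity correction.
#'
#' @param x,y Numeric samples.
#' @param exact_limit Largest combined n for exact enumeration (default 20).
#' @param correct Continuity correction in the normal branch.
#' @return An object of class `rank_test`: list with `U` (statistic for the
#'   first sample), `p_value`, `exact`, `n`.
#' @export
rank_test <- function(x, y, exact_limit = 20, correct = TRUE) {
  if (!length(x) || !length(y)) stopf("both groups must be non-empty")
  n1 <- length(x)
  n2 <- length(y)
  n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  center <- n1 * n2 / 2
  if (n <= exact_limit) {
    sets <- utils::combn(n, n1)
    usim <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(usim - center) >= abs(u - center) - 1e-9)
    exact <- TRUE
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    dev <- abs(u - center)
    if (correct) dev <- max(dev - 0.5, 0)
    p <- if (sigma2 == 0) 1 else min(2 * pnorm(-dev / sqrt(sigma2)), 1)
    exact <- FALSE
  }
  structure(list(U = u, p_value = p, exact = exact, n = c(n1, n2)),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d, %d), two-sided p = %.4g [%s]\n",
              x$U, x$n[1], x$n[2], x$p_value,
              if (x$exact) "exact enumeration" else "normal approximation"))
  invisible(x)
}
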