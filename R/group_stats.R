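## Monte-Carlo sample of the null max-|t| over many-to-one contrasts.
## ns: group sizes, control first. Under a common normal error variance the
## contrast t-statistics are jointly multivariate t; we sample them directly
## from group means and a pooled chi-square scale.
dunnett_maxabs_sample <- function(ns, df, mc_draws, seed) {
  k <- length(ns) - 1L
  withr::with_seed(seed, {
    means <- matrix(rnorm(mc_draws * length(ns)), nrow = mc_draws)
    means <- sweep(means, 2, sqrt(1 / ns), "*")
    s <- sqrt(rchisq(mc_draws, df) / df)
  })
  scale <- sqrt(1 / ns[-1] + 1 / ns[1])
  tmat <- (means[, -1, drop = FALSE] - means[, 1]) /
    (s %o% scale)
  do.call(pmax, lapply(seq_len(k), function(j) abs(tmat[, j])))
}

#' Dunnett many-to-one comparisons against a control
#'
#' One-way fixed-effects comparison of every group against a designated
#' control with a family-wise adjustment over the correlated contrasts:
#' each adjusted p-value is the probability, under the null, that the
#' maximum absolute contrast t-statistic exceeds the observed one
#' (the equicoordinate multivariate-t adjustment). That probability is
#' evaluated by seeded Monte Carlo; the per-contrast Monte-Carlo standard
#' error is reported (at the default 200,000 draws it is at most about
#' 1.1e-3, attained near p = 0.5; pass `mc_draws = 1e6` for ~5e-4).
#'
#' @param values Numeric observations.
#' @param groups Group labels, same length as `values`.
#' @param control Label of the control group.
#' @param alpha Significance level for the `significant` flag.
#' @param mc_draws Monte-Carlo draws for the max-|t| reference distribution.
#' @param seed Seed for the Monte-Carlo draws.
#' @return An object of class `dunnett_result`: data frame with one row per
#'   non-control group (`group`, `estimate` = mean difference vs control,
#'   `se`, `t`, `p_raw`, `p_adj`, `mc_se`, `significant`) with attributes
#'   `control`, `alpha`, `df`, `sigma2` (pooled residual variance), and
#'   `anova_p` (one-way ANOVA F-test p-value).
#' @export
dunnett_vs_control <- function(values, groups, control, alpha = 0.05,
                               mc_draws = 200000, seed = 1) {
  if (length(values) != length(groups))
    stopf("`values` and `groups` must have equal length")
  groups <- as.character(groups)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- groups[keep]
  labs <- unique(groups)
  if (!control %in% labs) stopf("control group '%s' not present", control)
  if (length(labs) < 2) stopf("need at least 2 groups")
  ns <- vapply(labs, function(g) sum(groups == g), integer(1))
  if (any(ns < 2))
    stopf("every group needs >= 2 observations; too few in: %s",
          paste(labs[ns < 2], collapse = ", "))
  labs <- c(control, setdiff(labs, control))
  ns <- ns[labs]
  means <- vapply(labs, function(g) mean(values[groups == g]), numeric(1))
  df <- length(values) - length(labs)
  sigma2 <- sum(vapply(labs, function(g) {
    v <- values[groups == g]
    sum((v - mean(v))^2)
  }, numeric(1))) / df
  if (sigma2 <= 0) stopf("zero residual variance: groups are constant")
  others <- labs[-1]
  est <- means[others] - means[[control]]
  se <- sqrt(sigma2 * (1 / ns[others] + 1 / ns[[control]]))
  tstat <- est / se
  p_raw <- 2 * pt(-abs(tstat), df)
  maxabs <- dunnett_maxabs_sample(ns, df, mc_draws, seed)
  p_adj <- vapply(tstat, function(t0) mean(maxabs >= abs(t0)), numeric(1))
  p_adj <- pmin(pmax(p_adj, p_raw), 1)
  mc_se <- sqrt(pmax(p_adj * (1 - p_adj), 0) / mc_draws)
  grand <- mean(values)
  ss_between <- sum(ns * (means - grand)^2)
  f <- (ss_between / (length(labs) - 1)) / sigma2
  res <- data.frame(group = others, estimate = unname(est),
                    se = unname(se), t = unname(tstat),
                    p_raw = unname(p_raw), p_adj = unname(p_adj),
                    mc_se = unname(mc_se),
                    significant = unname(p_adj < alpha),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("dunnett_result", "data.frame")
  attr(res, "control") <- control
  attr(res, "alpha") <- alpha
  attr(res, "df") <- df
  attr(res, "sigma2") <- sigma2
  attr(res, "anova_p") <- pf(f, length(labs) - 1, df, lower.tail = FALSE)
  res
}

#' Equicoordinate critical value for Dunnett contrasts
#'
#' The `1 - alpha` quantile of the null distribution of the maximum
#' absolute many-to-one contrast t-statistic, from the same seeded
#' Monte-Carlo sampler as [dunnett_vs_control()]. Useful for calibration
#' studies: a dataset produces a family-wise error exactly when its observed
#' max |t| exceeds this value.
#'
#' @param ns Group sizes, control first.
#' @param alpha Family-wise error rate.
#' @param mc_draws,seed Monte-Carlo settings.
#' @return The critical value (single number).
#' @export
dunnett_critical <- function(ns, alpha = 0.05, mc_draws = 200000, seed = 1) {
  df <- sum(ns) - length(ns)
  maxabs <- dunnett_maxabs_sample(ns, df, mc_draws, seed)
  unname(quantile(maxabs, 1 - alpha))
}

#' Mixed-model slope contrasts between genotypes
#'
#' Compares FLC decline slopes between genotypes with a REML linear mixed
#' model: `value ~ genotype * day + (1 | block)`, with the day covariate
#' centred to mean 0 before fitting so that genotype main effects are
#' evaluated mid-window. Each `genotype:day` interaction coefficient is the
#' difference between that genotype's slope and the reference genotype's
#' slope; t-tests use Satterthwaite-approximated denominator degrees of
#' freedom (via \pkg{lmerTest}).
#'
#' With a single block the random effect is unidentifiable and the function
#' falls back to an ordinary fixed-effects regression with a warning.
#'
#' @param data Long data frame with columns `genotype`, `day`, `block`, and
#'   the response (default column `value_au`).
#' @param reference Reference genotype label.
#' @param value_col Name of the response column.
#' @return An object of class `mixed_slope_result`: list with `contrasts`
#'   (data frame: genotype, estimate, se, df, t, p), `varcomp` (block and
#'   residual variances), `reference`, `method` (`"lmer"` or `"lm"`), and
#'   the fitted model in `fit`.
#' @export
mixed_slope_contrasts <- function(data, reference, value_col = "value_au") {
  assert_columns(data, c("genotype", "day", "block", value_col),
                 "long expression table")
  if (!reference %in% data$genotype)
    stopf("reference genotype '%s' not present", reference)
  if (length(unique(data$genotype)) < 2)
    stopf("need >= 2 genotypes including the reference")
  if (length(unique(data$day)) < 2) stopf("need >= 2 distinct days")
  d <- data.frame(genotype = stats::relevel(factor(data$genotype),
                                            ref = reference),
                  day_c = data$day - mean(data$day),
                  block = factor(data$block),
                  value = data[[value_col]])
  if (nlevels(d$block) < 2) {
    warnf("single block: falling back to fixed-effects regression")
    fit <- lm(value ~ genotype * day_c, data = d)
    ct <- summary(fit)$coefficients
    rows <- grepl("^genotype.*:day_c$", rownames(ct))
    contrasts <- data.frame(
      genotype = sub(":day_c$", "", sub("^genotype", "", rownames(ct)[rows])),
      estimate = ct[rows, "Estimate"], se = ct[rows, "Std. Error"],
      df = fit$df.residual, t = ct[rows, "t value"],
      p = ct[rows, "Pr(>|t|)"], row.names = NULL, stringsAsFactors = FALSE)
    varcomp <- c(block = 0, residual = summary(fit)$sigma^2)
    method <- "lm"
  } else {
    fit <- withCallingHandlers(
      suppressMessages(
        lmerTest::lmer(value ~ genotype * day_c + (1 | block), data = d,
                       REML = TRUE)),
      warning = function(w) {
        if (grepl("converge|unidentifiable|eigenvalue",
                  conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    ct <- coef(summary(fit))
    rows <- grepl("^genotype.*:day_c$", rownames(ct))
    contrasts <- data.frame(
      genotype = sub(":day_c$", "", sub("^genotype", "", rownames(ct)[rows])),
      estimate = ct[rows, "Estimate"], se = ct[rows, "Std. Error"],
      df = ct[rows, "df"], t = ct[rows, "t value"],
      p = ct[rows, "Pr(>|t|)"], row.names = NULL, stringsAsFactors = FALSE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    varcomp <- c(block = vc$vcov[vc$grp == "block"],
                 residual = vc$vcov[vc$grp == "Residual"])
    method <- "lmer"
  }
  structure(list(contrasts = contrasts, varcomp = varcomp,
                 reference = reference, method = method, fit = fit),
            class = "mixed_slope_result")
}

#' Asymptotic test for equality of coefficients of variation
#'
#' Tests whether k groups share a common coefficient of variation
#' (cv = sd/mean) with the asymptotic (Feltz-Miller) chi-square statistic:
#' with pooled cv the `(n_i - 1)`-weighted mean of the group cvs,
#' \deqn{D = \frac{\sum_i (n_i - 1)(cv_i - \bar{cv})^2}
#'                {\bar{cv}^2 (0.5 + \bar{cv}^2)}}
#' referred to a chi-square distribution with k - 1 degrees of freedom.
#' The statistic is invariant to positive rescaling of any group.
#'
#' @param groups List of numeric vectors (one per group, each n >= 2, mean
#'   not 0), optionally named.
#' @return An object of class `cv_test`: list with `statistic`, `df`,
#'   `p_value`, and a per-group `table` (n, mean, sd, cv).
#' @export
cv_equality_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stopf("`groups` must be a list of >= 2 numeric vectors")
  labs <- names(groups) %||% paste0("group", seq_along(groups))
  if (is.null(names(groups))) names(groups) <- labs
  n <- vapply(groups, length, integer(1))
  if (any(n < 2))
    stopf("every group needs n >= 2; too few in: %s",
          paste(labs[n < 2], collapse = ", "))
  m <- vapply(groups, mean, numeric(1))
  if (any(m == 0))
    stopf("group mean of 0 in: %s (cv undefined)",
          paste(labs[m == 0], collapse = ", "))
  s <- vapply(groups, sd, numeric(1))
  cv <- s / m
  w <- n - 1
  cvbar <- sum(w * cv) / sum(w)
  statistic <- if (cvbar == 0) 0 else
    sum(w * (cv - cvbar)^2) / (cvbar^2 * (0.5 + cvbar^2))
  df <- length(groups) - 1
  structure(list(statistic = statistic, df = df,
                 p_value = pchisq(statistic, df, lower.tail = FALSE),
                 table = data.frame(group = labs, n = n, mean = m, sd = s,
                                    cv = cv, row.names = NULL,
                                    stringsAsFactors = FALSE)),
            class = "cv_test")
}

#' @export
print.cv_test <- function(x, ...) {
  cat(sprintf("Asymptotic CV-equality test: chi-sq = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  print(x$table, ...)
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up procedure: with sorted p-values `p_(1) <= ... <= p_(m)`, reject
#' all hypotheses up to the largest k with `p_(k) <= k q / m`. Adjusted
#' p-values are the standard BH values (`stats::p.adjust`); a hypothesis is
#' rejected exactly when its adjusted p-value is at most `q`.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param q Target false discovery rate.
#' @return List with `reject` (logical, in input order), `p_adjusted`, `q`.
#' @export
bh_adjust <- function(p, q = 0.05) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1] with no NA")
  assert_number(q, "q", lower = 0, upper = 1)
  adj <- p.adjust(p, method = "BH")
  list(reject = adj <= q, p_adjusted = adj, q = q)
}

#' Variability comparison of decay features across groups
#'
#' Computes the coefficient of variation of each decay feature (starting
#' levels, VIN3-independent, VIN3-dependent and combined rates) over the
#' genotype-level point estimates within each site x year, then tests
#' (a) within each site x year, whether the available features share a
#' common CV, and (b) for each feature, whether its CV is equal across
#' site x years -- all with [cv_equality_test()] and joint
#' Benjamini-Hochberg correction. Rates enter as magnitudes (absolute
#' values), since variability, not sign, is compared.
#'
#' @param features A [extract_features()] result (rows from several
#'   site x years may be concatenated).
#' @param genotypes Optional subset of genotypes to include (e.g. accessions
#'   only, or NILs plus the reference).
#' @param q False discovery rate for [bh_adjust()].
#' @return List with `cv` (per site x year x feature CV table), `tests`
#'   (comparison, statistic, df, p, p_adj, reject), and `skipped`
#'   (comparisons not run, with reasons).
#' @export
variability_report <- function(features, genotypes = NULL, q = 0.05) {
  assert_columns(features, c("genotype", "starting_level"), "features table")
  if (!is.null(genotypes))
    features <- features[features$genotype %in% genotypes, , drop = FALSE]
  if (!"site" %in% names(features)) features$site <- "site"
  if (!"year" %in% names(features)) features$year <- NA
  feature_cols <- c(starting = "starting_level", vindep = "rate_vindep",
                    vdep = "rate_vdep", combined = "combined_rate")
  feature_cols <- feature_cols[feature_cols %in% names(features)]
  sy <- unique(features[, c("site", "year"), drop = FALSE])
  cv_rows <- list()
  groups_by_sy <- list()
  for (i in seq_len(nrow(sy))) {
    sel <- features$site == sy$site[i] &
      (is.na(sy$year[i]) | features$year == sy$year[i])
    sub <- features[sel, , drop = FALSE]
    gl <- list()
    for (f in names(feature_cols)) {
      vals <- abs(na.omit(sub[[feature_cols[[f]]]]))
      if (length(vals) >= 2) gl[[f]] <- as.numeric(vals)
      cv_rows[[length(cv_rows) + 1]] <- data.frame(
        site = sy$site[i], year = sy$year[i], feature = f,
        n = length(vals),
        cv = if (length(vals) >= 2) sd(vals) / mean(vals) else NA_real_,
        stringsAsFactors = FALSE)
    }
    groups_by_sy[[paste(sy$site[i], sy$year[i])]] <- gl
  }
  cv_tab <- do.call(rbind, cv_rows)
  tests <- list()
  skipped <- list()
  add_test <- function(label, gl) {
    if (length(gl) < 2) {
      skipped[[length(skipped) + 1]] <<- data.frame(
        comparison = label, reason = "fewer than 2 groups of size >= 2",
        stringsAsFactors = FALSE)
      return(invisible())
    }
    tst <- cv_equality_test(gl)
    tests[[length(tests) + 1]] <<- data.frame(
      comparison = label, groups = paste(names(gl), collapse = "|"),
      statistic = tst$statistic, df = tst$df, p = tst$p_value,
      stringsAsFactors = FALSE)
  }
  for (nm in names(groups_by_sy))
    add_test(sprintf("features within %s", nm), groups_by_sy[[nm]])
  for (f in names(feature_cols)) {
    gl <- lapply(groups_by_sy, function(g) g[[f]])
    gl <- gl[!vapply(gl, is.null, logical(1))]
    add_test(sprintf("%s across site-years", f), gl)
  }
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(comparison = character(), groups = character(),
               statistic = numeric(), df = integer(), p = numeric(),
               stringsAsFactors = FALSE)
  if (nrow(tests)) {
    bh <- bh_adjust(tests$p, q)
    tests$p_adj <- bh$p_adjusted
    tests$reject <- bh$reject
  }
  list(cv = cv_tab, tests = tests,
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(comparison = character(), reason = character(),
                    stringsAsFactors = FALSE),
       rate_sign = "magnitudes")
}
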