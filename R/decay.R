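#' Starting level of FLC at the first field timepoint
#'
#' The "starting level" is the mean normalized FLC abundance at the earliest
#' sampled day. It is measured after some days in the field, so it is not a
#' true non-vernalized baseline: some VIN3-independent shutdown will already
#' have occurred.
#'
#' @param expression Expression table with columns `day`, `value_au`, and
#'   the grouping columns.
#' @param group_cols Grouping columns (default `"genotype"`).
#' @return Data frame with one row per group: the grouping columns,
#'   `day_first`, `starting_level` (mean), `starting_se` (sd/sqrt(n); `NA`
#'   for n = 1), and `n`.
#' @export
starting_level <- function(expression, group_cols = "genotype") {
  assert_columns(expression, c("day", "value_au", group_cols),
                 "expression table")
  day1 <- min(expression$day)
  groups <- unique(expression[, group_cols, drop = FALSE])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- rep(TRUE, nrow(expression))
    for (gc in group_cols)
      sel <- sel & expression[[gc]] == groups[[gc]][i]
    vals <- expression$value_au[sel & expression$day == day1]
    if (!length(vals))
      stopf("no records at first timepoint (day %g) for %s", day1,
            paste(unlist(groups[i, , drop = FALSE]), collapse = "/"))
    n <- length(vals)
    data.frame(groups[i, , drop = FALSE], day_first = day1,
               starting_level = mean(vals),
               starting_se = if (n > 1) sd(vals) / sqrt(n) else NA_real_,
               n = n, row.names = NULL, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit a phase-specific decline rate by linear regression
#'
#' Ordinary least-squares regression of expression (or log expression) on
#' day over the records whose day lies in `window` (inclusive). Replicates
#' enter as individual points. The slope is negative for declining series;
#' rate magnitudes are `-slope`.
#'
#' @param day,value Replicate-level observations.
#' @param window `c(day_lo, day_hi)` window, or `NULL` for all days.
#' @param scale `"linear"` (slope in a.u./day) or `"log"` (slope in /day;
#'   all values in the window must be > 0).
#' @return An object of class `phase_rate_fit`: list with `slope`, `se`
#'   (`NA` with zero residual degrees of freedom, i.e. 2 points),
#'   `intercept` (at day 0), `n`, `n_days`, `df`, `window`, `scale`.
#' @export
fit_phase_rate <- function(day, value, window = NULL,
                           scale = c("linear", "log")) {
  scale <- match.arg(scale)
  if (length(day) != length(value))
    stopf("`day` and `value` must have equal length")
  keep <- !is.na(day) & !is.na(value)
  if (!is.null(window)) keep <- keep & day >= window[1] & day <= window[2]
  day <- day[keep]
  value <- value[keep]
  n_days <- length(unique(day))
  if (n_days < 2)
    stopf("need >= 2 distinct days in the window, got %d", n_days)
  if (scale == "log") {
    bad <- which(value <= 0)
    if (length(bad))
      stopf("log-scale fit requires positive values; offending record(s): %s",
            paste(sprintf("(day %g, value %g)", day[bad], value[bad]),
                  collapse = ", "))
    value <- log(value)
  }
  fit <- lm(value ~ day)
  sm <- suppressWarnings(summary(fit))$coefficients
  se <- if (fit$df.residual > 0) sm["day", "Std. Error"] else NA_real_
  structure(list(slope = unname(coef(fit)[["day"]]), se = se,
                 intercept = unname(coef(fit)[["(Intercept)"]]),
                 n = length(day), n_days = n_days, df = fit$df.residual,
                 window = window, scale = scale),
            class = "phase_rate_fit")
}

resolve_breakpoint <- function(breakpoint) {
  if (is.null(breakpoint)) return(NULL)
  if (inherits(breakpoint, "breakpoint_estimate")) {
    if (!breakpoint$detected)
      stopf("breakpoint estimate has detected = FALSE; supply a fixed day or use combined mode")
    return(breakpoint$day)
  }
  assert_number(breakpoint, "breakpoint")
  breakpoint
}

#' Extract decay features per genotype
#'
#' Decomposes each genotype's FLC time course into the three profile
#' features: starting level, VIN3-independent rate (days at or before the
#' breakpoint) and VIN3-dependent rate (days after it). In `"combined"`
#' mode -- appropriate when the two phases occur concurrently and a single
#' decline is seen -- one rate is fitted over all retained days.
#' `exclude_after_day` drops trailing timepoints before fitting (used when
#' late-winter warming reactivates FLC in some genotypes and the decline
#' model no longer applies).
#'
#' A phase window with fewer than 2 distinct days yields `NA` rates with the
#' reason recorded, never a silent `NaN`.
#'
#' @param expression Expression table (columns `day`, `value_au`, `gene` if
#'   present, and the grouping columns).
#' @param breakpoint Numeric day, or a [detect_induction()] result; required
#'   for `mode = "two_phase"`. The breakpoint day itself is assigned to the
#'   VIN3-independent window (configurable via `breakpoint_in`).
#' @param mode `"two_phase"` or `"combined"`.
#' @param scale Regression scale, `"linear"` or `"log"`; see
#'   [fit_phase_rate()].
#' @param exclude_after_day Drop records after this day (`NULL` = keep all).
#' @param gene Gene to analyse when a `gene` column is present.
#' @param group_cols Grouping columns present in `expression`.
#' @param breakpoint_in Which window receives the breakpoint day itself:
#'   `"vindep"` (day <= breakpoint, default) or `"vdep"`.
#' @return A data frame of class `decay_features` with one row per group:
#'   starting level (with se, n), `rate_vindep`, `rate_vdep` or
#'   `combined_rate` (slopes, negative for decline, with se and n), `mode`,
#'   `scale`, `exclusion_after_day`, and `reason` for unavailable features.
#' @export
extract_features <- function(expression, breakpoint = NULL,
                             mode = c("two_phase", "combined"),
                             scale = c("linear", "log"),
                             exclude_after_day = NULL, gene = "FLC_spliced",
                             group_cols = intersect(c("genotype", "site",
                                                      "year"),
                                                    names(expression)),
                             breakpoint_in = c("vindep", "vdep")) {
  mode <- match.arg(mode)
  scale <- match.arg(scale)
  breakpoint_in <- match.arg(breakpoint_in)
  assert_columns(expression, c("day", "value_au", group_cols),
                 "expression table")
  if ("gene" %in% names(expression))
    expression <- expression[expression$gene == gene, , drop = FALSE]
  if (!nrow(expression))
    stopf("no expression records for gene '%s'", gene)
  bp <- resolve_breakpoint(breakpoint)
  if (mode == "two_phase" && is.null(bp))
    stopf("two-phase mode requires a breakpoint")
  start <- starting_level(expression, group_cols)
  if (!is.null(exclude_after_day))
    expression <- expression[expression$day <= exclude_after_day, ,
                             drop = FALSE]
  try_rate <- function(day, value, window) {
    tryCatch({
      f <- fit_phase_rate(day, value, window, scale)
      list(slope = f$slope, se = f$se, n = f$n, reason = NA_character_)
    }, error = function(e) {
      list(slope = NA_real_, se = NA_real_, n = 0L,
           reason = conditionMessage(e))
    })
  }
  rows <- lapply(seq_len(nrow(start)), function(i) {
    sel <- rep(TRUE, nrow(expression))
    for (gc in group_cols)
      sel <- sel & expression[[gc]] == start[[gc]][i]
    d <- expression$day[sel]
    v <- expression$value_au[sel]
    base <- start[i, , drop = FALSE]
    names(base)[names(base) == "n"] <- "starting_n"
    if (mode == "two_phase") {
      pre <- if (breakpoint_in == "vindep") d <= bp else d < bp
      f1 <- try_rate(d[pre], v[pre], NULL)
      f2 <- try_rate(d[!pre], v[!pre], NULL)
      reason <- c(if (!is.na(f1$reason))
        sprintf("rate_vindep unavailable: %s", f1$reason),
        if (!is.na(f2$reason))
          sprintf("rate_vdep unavailable: %s", f2$reason))
      data.frame(base, rate_vindep = f1$slope, rate_vindep_se = f1$se,
                 rate_vindep_n = f1$n, rate_vdep = f2$slope,
                 rate_vdep_se = f2$se, rate_vdep_n = f2$n,
                 combined_rate = NA_real_, combined_se = NA_real_,
                 combined_n = NA_integer_, mode = mode, scale = scale,
                 exclusion_after_day = exclude_after_day %||% NA_real_,
                 reason = if (length(reason)) paste(reason, collapse = "; ")
                 else NA_character_,
                 row.names = NULL, stringsAsFactors = FALSE)
    } else {
      f <- try_rate(d, v, NULL)
      data.frame(base, rate_vindep = NA_real_, rate_vindep_se = NA_real_,
                 rate_vindep_n = NA_integer_, rate_vdep = NA_real_,
                 rate_vdep_se = NA_real_, rate_vdep_n = NA_integer_,
                 combined_rate = f$slope, combined_se = f$se,
                 combined_n = f$n, mode = mode, scale = scale,
                 exclusion_after_day = exclude_after_day %||% NA_real_,
                 reason = if (!is.na(f$reason))
                   sprintf("combined rate unavailable: %s", f$reason)
                 else NA_character_,
                 row.names = NULL, stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("decay_features", "data.frame")
  attr(res, "breakpoint") <- bp
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
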