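#' Detect the day of substantial VIN3 induction
#'
#' Estimates the site-level day on which VIN3 is substantially upregulated,
#' which splits the VIN3-independent and VIN3-dependent windows of FLC
#' shutdown. The rule is: take the median of the first `baseline_points`
#' per-day mean values as the baseline; set the threshold to
#' `max(baseline * fold, floor)`; report the first sampled day at which the
#' mean value exceeds the threshold for `min_consecutive` consecutive
#' timepoints. VIN3 fluctuates with the temperature profile, so the
#' consecutive-exceedance requirement guards against single warm-spell
#' spikes. By convention the breakpoint is estimated from the reference
#' genotype (Col FRI) and shared across genotypes at a site, since induction
#' timing is very similar between genotypes at the same site; a fixed day
#' may be used instead wherever a `breakpoint` is accepted downstream.
#'
#' If no day satisfies the rule (e.g. mutants with delayed VIN3), the result
#' has `detected = FALSE` rather than raising an error.
#'
#' @param series Data frame with columns `day` and `value_au` (or `value`),
#'   replicate-level or per-day means; replicates are averaged per day.
#' @param baseline_points Number of initial timepoints defining the baseline
#'   (default 3).
#' @param fold Fold over baseline required for induction (default 3).
#' @param min_consecutive Consecutive above-threshold timepoints required
#'   (default 2).
#' @param floor Absolute threshold floor in a.u. (default 0.05); set to 0 to
#'   make detection fully scale-invariant.
#' @return An object of class `breakpoint_estimate`: list with `day`,
#'   `baseline`, `threshold`, `method`, `detected`, and `supported`
#'   (at least 2 timepoints at or after the detected day, so that the
#'   post-induction phase can be fitted).
#' @export
detect_induction <- function(series, baseline_points = 3, fold = 3,
                             min_consecutive = 2, floor = 0.05) {
  if (!is.data.frame(series)) stopf("`series` must be a data frame")
  vcol <- if ("value_au" %in% names(series)) "value_au" else "value"
  assert_columns(series, c("day", vcol), "VIN3 series")
  assert_number(baseline_points, "baseline_points", lower = 1)
  assert_number(fold, "fold", lower = 0, strict_lower = TRUE)
  assert_number(min_consecutive, "min_consecutive", lower = 1)
  assert_number(floor, "floor", lower = 0)
  if (any(series[[vcol]] < 0)) stopf("VIN3 values must be >= 0")
  agg <- stats::aggregate(stats::setNames(list(series[[vcol]]), "value"),
                          by = list(day = series$day), FUN = mean)
  agg <- agg[order(agg$day), , drop = FALSE]
  n <- nrow(agg)
  if (n < baseline_points + min_consecutive)
    stopf("need at least baseline_points + min_consecutive = %d timepoints, got %d",
          baseline_points + min_consecutive, n)
  baseline <- median(agg$value[seq_len(baseline_points)])
  threshold <- max(baseline * fold, floor)
  above <- agg$value > threshold
  day <- NA_real_
  for (i in seq_len(n - min_consecutive + 1)) {
    if (all(above[i:(i + min_consecutive - 1)])) {
      day <- agg$day[i]
      break
    }
  }
  detected <- !is.na(day)
  structure(list(day = day, baseline = baseline, threshold = threshold,
                 method = "fold-over-baseline", detected = detected,
                 supported = detected && sum(agg$day >= day) >= 2),
            class = "breakpoint_estimate")
}

#' @export
print.breakpoint_estimate <- function(x, ...) {
  if (x$detected) {
    cat(sprintf(
      "VIN3 induction detected at day %g (baseline %.3g, threshold %.3g)%s\n",
      x$day, x$baseline, x$threshold,
      if (x$supported) "" else " [unsupported: <2 post-induction timepoints]"))
  } else {
    cat(sprintf("no VIN3 induction detected (baseline %.3g, threshold %.3g)\n",
                x$baseline, x$threshold))
  }
  invisible(x)
}
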