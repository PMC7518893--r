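#' Fit the FLC post-vernalization statistic for one genotype
#'
#' Ordinary least-squares regression of mean days-to-bolting on mean FLC at
#' transfer across transfer dates: `days to bolting = m * FLC + c`. The
#' slope `m` is the "FLC post-vern" value (days to bolting per FLC unit);
#' the intercept `c` captures non-FLC-mediated bolting delay, dependent on
#' the transfer dates and glasshouse conditions.
#'
#' With exactly 2 points the slope and intercept are exact but no standard
#' error is calculable (se and p are `NA`, `reliable = FALSE`). A fit is
#' flagged unreliable when the slope's p-value exceeds 0.1 or is
#' unavailable. Genotypes whose FLC values never exceed `low_flc_threshold`
#' (too low to cause measurable bolting differences, as for a
#' non-functional-FLC genotype) are flagged `low_flc`; zero FLC spread makes
#' the slope inestimable.
#'
#' @param flc Mean FLC at transfer (a.u.), one value per transfer date.
#' @param bolting Mean days to bolting, same length.
#' @param genotype,site Labels carried into the result.
#' @param low_flc_threshold FLC level below which the genotype is flagged
#'   as having too little FLC for estimation (default 0.05 a.u.).
#' @return An object of class `postvern_fit`: list with `genotype`, `site`,
#'   `m`, `c`, `se_m`, `p_m`, `n_points`, `reliable`, `low_flc`, `reason`.
#' @export
fit_postvern <- function(flc, bolting, genotype = NA_character_,
                         site = NA_character_, low_flc_threshold = 0.05) {
  keep <- !is.na(flc) & !is.na(bolting)
  flc <- flc[keep]
  bolting <- bolting[keep]
  n <- length(flc)
  if (n < 2 || length(bolting) != n)
    stopf("need >= 2 (FLC, bolting) points, got %d", n)
  low_flc <- all(flc < low_flc_threshold)
  out <- list(genotype = genotype, site = site, m = NA_real_, c = NA_real_,
              se_m = NA_real_, p_m = NA_real_, n_points = n,
              reliable = FALSE, low_flc = low_flc, reason = NA_character_)
  if (max(flc) - min(flc) < .Machine$double.eps^0.5 * max(abs(flc), 1)) {
    out$reason <- "inestimable (no FLC spread)"
    return(structure(out, class = "postvern_fit"))
  }
  fit <- lm(bolting ~ flc)
  out$m <- unname(coef(fit)[["flc"]])
  out$c <- unname(coef(fit)[["(Intercept)"]])
  if (fit$df.residual > 0) {
    sm <- suppressWarnings(summary(fit))$coefficients
    out$se_m <- sm["flc", "Std. Error"]
    out$p_m <- sm["flc", "Pr(>|t|)"]
    out$reliable <- is.finite(out$p_m) && out$p_m <= 0.1
    if (!out$reliable) out$reason <- "unreliable (p > 0.1)"
  } else {
    out$reason <- "two points: no standard error calculable"
  }
  if (low_flc) {
    out$reliable <- FALSE
    out$reason <- paste(na.omit(c(out$reason, "FLC too low for estimation")),
                        collapse = "; ")
  }
  structure(out, class = "postvern_fit")
}

#' @export
print.postvern_fit <- function(x, ...) {
  cat(sprintf("FLC post-vern fit%s%s: m = %.4g, c = %.4g (n = %d%s)\n",
              if (!is.na(x$genotype)) paste0(" [", x$genotype, "]") else "",
              if (!is.na(x$site)) paste0(" @", x$site) else "",
              x$m, x$c, x$n_points,
              if (!is.na(x$reason)) paste0("; ", x$reason) else ""))
  invisible(x)
}

#' Per-genotype post-vern fits from a transfer experiment table
#'
#' Aggregates a plant-level transfer table to genotype x transfer-date means
#' (excluding censored DNF plants, and dead plants if a `dead` column is
#' present) and fits [fit_postvern()] per genotype. The number of excluded
#' plants is reported per fit.
#'
#' @param transfers Data frame with columns `genotype`, `transfer_day`,
#'   `days_to_bolting` (`NA` when not observed), a censoring flag `dnf`,
#'   and an FLC-at-transfer column.
#' @param flc_col Which FLC column to regress on (default
#'   `"flc_at_transfer"`).
#' @param site Site label carried into the fits.
#' @param low_flc_threshold Passed to [fit_postvern()].
#' @return A list of `postvern_fit` objects, one per genotype, each with an
#'   `n_excluded` element added.
#' @export
postvern_from_transfers <- function(transfers, flc_col = "flc_at_transfer",
                                    site = NA_character_,
                                    low_flc_threshold = 0.05) {
  assert_columns(transfers, c("genotype", "transfer_day", "days_to_bolting",
                              flc_col), "transfer table")
  if (is.null(transfers$dnf)) transfers$dnf <- FALSE
  excluded <- transfers$dnf | is.na(transfers$days_to_bolting)
  if (!is.null(transfers$dead)) excluded <- excluded | transfers$dead
  fits <- lapply(unique(transfers$genotype), function(g) {
    sub <- transfers[transfers$genotype == g, , drop = FALSE]
    excl <- excluded[transfers$genotype == g]
    kept <- sub[!excl, , drop = FALSE]
    days <- sort(unique(kept$transfer_day))
    if (length(days) < 2) {
      # the Löv-1-in-the-North case: plants did not bolt within follow-up
      # at enough transfer dates, so no slope is estimable ("n.d.")
      fit <- structure(list(genotype = g, site = site, m = NA_real_,
                            c = NA_real_, se_m = NA_real_, p_m = NA_real_,
                            n_points = length(days), reliable = FALSE,
                            low_flc = FALSE,
                            reason = "fewer than 2 transfer dates with observed bolting (n.d.)"),
                       class = "postvern_fit")
      fit$n_excluded <- sum(excl)
      return(fit)
    }
    mean_flc <- vapply(days, function(d)
      mean(kept[[flc_col]][kept$transfer_day == d]), numeric(1))
    mean_bolt <- vapply(days, function(d)
      mean(kept$days_to_bolting[kept$transfer_day == d]), numeric(1))
    fit <- fit_postvern(mean_flc, mean_bolt, genotype = g, site = site,
                        low_flc_threshold = low_flc_threshold)
    fit$n_excluded <- sum(excl)
    fit
  })
  names(fits) <- unique(transfers$genotype)
  fits
}

#' Average the post-vern statistic across sites
#'
#' Arithmetic mean of the available per-site `m` estimates for one genotype.
#' Averaging is done on unrounded values; use [round_half_up()] only for
#' display. A genotype measured at a single site returns that site's `m`.
#'
#' @param fits Numeric vector of per-site `m` values, or a list of
#'   `postvern_fit` objects.
#' @return List with `m` (the cross-site average), `n_sites`, and `sites`
#'   (contributing site labels, when available).
#' @export
average_postvern <- function(fits) {
  if (is.list(fits) && all(vapply(fits, inherits, logical(1),
                                  "postvern_fit"))) {
    m <- vapply(fits, `[[`, numeric(1), "m")
    sites <- vapply(fits, function(f) as.character(f$site), character(1))
  } else if (is.numeric(fits)) {
    m <- fits
    sites <- rep(NA_character_, length(m))
  } else {
    stopf("`fits` must be numeric m values or a list of postvern_fit objects")
  }
  ok <- is.finite(m)
  if (!any(ok)) stopf("no estimable site-level m value")
  list(m = mean(m[ok]), n_sites = sum(ok), sites = sites[ok])
}
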