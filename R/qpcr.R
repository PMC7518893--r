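#' qPCR quality-control thresholds
#'
#' @param reference_cq_max Reference-gene Cq above which a sample is flagged
#'   as possibly degraded (default 28).
#' @param duplicate_cq_spread_max Maximum tolerated Cq spread between
#'   technical replicates of one amplicon (default 0.6 cycles).
#' @param anomaly_fold Fold change relative to the group median beyond which
#'   a target measurement counts as anomalous (default 10, i.e. an order of
#'   magnitude).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(reference_cq_max = 28,
                          duplicate_cq_spread_max = 0.6,
                          anomaly_fold = 10) {
  assert_number(reference_cq_max, "reference_cq_max", lower = 0,
                strict_lower = TRUE)
  assert_number(duplicate_cq_spread_max, "duplicate_cq_spread_max",
                lower = 0, strict_lower = TRUE)
  assert_number(anomaly_fold, "anomaly_fold", lower = 0, strict_lower = TRUE)
  structure(list(reference_cq_max = reference_cq_max,
                 duplicate_cq_spread_max = duplicate_cq_spread_max,
                 anomaly_fold = anomaly_fold),
            class = "qc_thresholds")
}

#' Convert quantification cycles to relative starting concentration
#'
#' `conc = efficiency^(-cq)`: one cycle fewer at efficiency 2 means twice
#' the template. Per-well efficiency estimation from fluorescence curves is
#' upstream of this package; `efficiency` is a per-run constant.
#'
#' @param cq Quantification-cycle values.
#' @param efficiency Amplification efficiency in (1, 2].
#' @return Relative starting concentrations (a.u.).
#' @export
cq_to_conc <- function(cq, efficiency = 2) {
  assert_number(efficiency, "efficiency", lower = 1, strict_lower = TRUE)
  efficiency^(-cq)
}

#' Normalize a target concentration to reference genes
#'
#' Divides the target's starting concentration by the geometric mean of the
#' reference-gene concentrations (typically PP2A and UBC).
#'
#' @param target_conc Target starting concentration (a.u., > 0).
#' @param reference_concs Numeric vector of reference concentrations (> 0).
#' @return Normalized expression (a.u.).
#' @export
normalize_to_references <- function(target_conc, reference_concs) {
  assert_number(target_conc, "target_conc", lower = 0, strict_lower = TRUE)
  if (!length(reference_concs)) stopf("at least one reference is required")
  bad <- which(!is.finite(reference_concs) | reference_concs <= 0)
  if (length(bad))
    stopf("non-positive reference concentration at position(s) %s",
          paste(bad, collapse = ", "))
  target_conc / geometric_mean(reference_concs)
}

#' Calibrate a set of values to a designated control sample
#'
#' Divides every value by the value of the control sample, so that the
#' control maps to exactly 1. Calibrating plates that share a common control
#' sample makes their values directly comparable, and preserves all
#' within-plate ratios exactly.
#'
#' @param values Named numeric vector of normalized values (> 0).
#' @param control_key Name of the control sample within `values`.
#' @return Calibrated values (same names); the control is exactly 1.
#' @export
calibrate_to_control <- function(values, control_key) {
  if (is.null(names(values))) stopf("`values` must be a named vector")
  if (!control_key %in% names(values))
    stopf("control sample '%s' not found", control_key)
  ctl <- values[[control_key]]
  if (!is.finite(ctl) || ctl <= 0)
    stopf("control sample '%s' has non-positive value %g", control_key, ctl)
  values / ctl
}

record_conc <- function(records, efficiency) {
  conc <- records$starting_conc
  if (is.null(conc)) conc <- rep(NA_real_, nrow(records))
  if (!is.null(records$cq)) {
    use_cq <- is.na(conc) & !is.na(records$cq)
    conc[use_cq] <- cq_to_conc(records$cq[use_cq], efficiency)
  }
  conc
}

#' Apply qPCR quality filters
#'
#' Implements two exclusion rules on technical-replicate-level qPCR records:
#' \enumerate{
#'   \item Duplicate spread: technical replicates of one sample x amplicon
#'     whose Cq values differ by more than `duplicate_cq_spread_max` are
#'     excluded, unless a retest record (`retest = TRUE`) is present for
#'     that sample x amplicon, in which case the retest is kept.
#'   \item High reference Cq: a sample whose reference-gene Cq exceeds
#'     `reference_cq_max` (possible degradation) is excluded only if a
#'     target amplicon is also anomalous -- missing, or outside
#'     `[median / anomaly_fold, median * anomaly_fold]` of the non-flagged
#'     samples of the same group (genotype x timepoint by default).
#'     A high reference Cq alone leads to a `high_reference_cq` flag, not
#'     exclusion.
#' }
#' Filtering is idempotent: applying it to its own output changes nothing.
#'
#' @param records Data frame with columns `sample_id`, `amplicon`,
#'   `technical_rep`, at least one of `cq` / `starting_conc`, optionally
#'   `retest` (logical) and the grouping columns.
#' @param thresholds A [qc_thresholds()].
#' @param reference_amplicons Amplicon labels of the reference genes.
#' @param group_cols Columns defining peer groups for the anomaly check.
#' @param efficiency Amplification efficiency used when only Cq is given.
#' @return List with `kept` (records plus a `qc_flags` column) and
#'   `exclusions` (data frame sample_id, amplicon, rule, detail).
#' @export
quality_filter <- function(records, thresholds = qc_thresholds(),
                           reference_amplicons = c("UBC", "PP2A"),
                           group_cols = c("genotype", "day"),
                           efficiency = 2) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  empty_log <- data.frame(sample_id = character(), amplicon = character(),
                          rule = character(), detail = character(),
                          stringsAsFactors = FALSE)
  if (is.null(records) || nrow(records) == 0) {
    kept <- if (is.null(records)) data.frame() else records
    if (nrow(kept) == 0 && !("qc_flags" %in% names(kept)) && ncol(kept) > 0)
      kept$qc_flags <- character(0)
    return(list(kept = kept, exclusions = empty_log))
  }
  assert_columns(records, c("sample_id", "amplicon"), "qPCR records")
  if (is.null(records$cq) && is.null(records$starting_conc))
    stopf("qPCR records need at least one of `cq` or `starting_conc`")
  if (!is.null(records$cq) && any(!is.na(records$cq) & records$cq <= 0))
    stopf("`cq` values must be > 0")
  if (is.null(records$retest)) records$retest <- FALSE
  if (is.null(records$qc_flags)) records$qc_flags <- ""
  group_cols <- intersect(group_cols, names(records))
  log <- empty_log
  drop <- rep(FALSE, nrow(records))

  ## Rule 1: technical-replicate Cq spread (primaries only; retests exempt)
  if (!is.null(records$cq)) {
    key <- paste(records$sample_id, records$amplicon, sep = "\r")
    for (k in unique(key)) {
      rows <- which(key == k & !records$retest)
      cqs <- records$cq[rows]
      cqs <- cqs[!is.na(cqs)]
      if (length(cqs) >= 2) {
        spread <- max(cqs) - min(cqs)
        if (spread > thresholds$duplicate_cq_spread_max) {
          has_retest <- any(key == k & records$retest)
          drop[rows] <- TRUE
          log <- rbind(log, data.frame(
            sample_id = records$sample_id[rows[1]],
            amplicon = records$amplicon[rows[1]],
            rule = "duplicate-spread",
            detail = sprintf("cq spread %.3g > %.3g%s", spread,
                             thresholds$duplicate_cq_spread_max,
                             if (has_retest) "; retest kept" else ""),
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  records2 <- records[!drop, , drop = FALSE]

  ## Rule 2: high reference Cq + anomalous target
  if (!is.null(records2$cq)) {
    conc <- record_conc(records2, efficiency)
    is_ref <- records2$amplicon %in% reference_amplicons
    high_ref <- records2$sample_id[is_ref & !is.na(records2$cq) &
                                     records2$cq > thresholds$reference_cq_max]
    high_ref <- unique(high_ref)
    if (length(high_ref)) {
      samp_meta <- records2[!duplicated(records2$sample_id),
                            c("sample_id", group_cols), drop = FALSE]
      gkey <- do.call(paste, c(samp_meta[, group_cols, drop = FALSE],
                               sep = "\r"))
      names(gkey) <- samp_meta$sample_id
      targets <- setdiff(unique(records2$amplicon), reference_amplicons)
      drop_sample <- character()
      for (s in high_ref) {
        anomaly <- NULL
        for (a in targets) {
          mine <- which(records2$sample_id == s & records2$amplicon == a)
          my_conc <- conc[mine]
          my_conc <- my_conc[is.finite(my_conc)]
          if (!length(my_conc)) {
            anomaly <- sprintf("target %s missing", a)
            break
          }
          peers <- which(records2$amplicon == a &
                           !(records2$sample_id %in% high_ref) &
                           gkey[records2$sample_id] == gkey[s])
          peer_conc <- conc[peers]
          peer_conc <- peer_conc[is.finite(peer_conc)]
          if (!length(peer_conc)) next
          med <- median(peer_conc)
          mc <- mean(my_conc)
          if (mc < med / thresholds$anomaly_fold ||
              mc > med * thresholds$anomaly_fold) {
            anomaly <- sprintf("target %s %.3g-fold from peer median", a,
                               max(mc / med, med / mc))
            break
          }
        }
        if (!is.null(anomaly)) {
          drop_sample <- c(drop_sample, s)
          log <- rbind(log, data.frame(
            sample_id = s, amplicon = "(all)",
            rule = "high-reference-cq+anomalous", detail = anomaly,
            stringsAsFactors = FALSE))
        } else {
          rows <- records2$sample_id == s
          records2$qc_flags[rows] <- ifelse(
            grepl("high_reference_cq", records2$qc_flags[rows]),
            records2$qc_flags[rows],
            sub("^;", "", paste(records2$qc_flags[rows],
                                "high_reference_cq", sep = ";")))
        }
      }
      records2 <- records2[!(records2$sample_id %in% drop_sample), ,
                           drop = FALSE]
    }
  }
  rownames(records2) <- NULL
  list(kept = records2, exclusions = log)
}

#' Normalize a table of qPCR records to reference genes
#'
#' Collapses technical replicates (geometric mean of concentrations), then
#' divides each target amplicon by the geometric mean of the sample's
#' reference amplicons.
#'
#' @param records qPCR records as for [quality_filter()] (normally its
#'   `kept` output).
#' @param reference_amplicons Reference-gene amplicon labels.
#' @param efficiency Amplification efficiency used when only Cq is present.
#' @param keep_cols Extra per-sample columns to carry through.
#' @return Data frame with one row per sample x target gene: the carried
#'   columns, `sample_id`, `gene`, `value_au`.
#' @export
normalize_samples <- function(records, reference_amplicons = c("UBC", "PP2A"),
                              efficiency = 2,
                              keep_cols = c("genotype", "site", "year",
                                            "day", "block")) {
  assert_columns(records, c("sample_id", "amplicon"), "qPCR records")
  conc <- record_conc(records, efficiency)
  if (any(!is.finite(conc)))
    stopf("record(s) without usable cq or starting_conc: row(s) %s",
          paste(which(!is.finite(conc)), collapse = ", "))
  keep_cols <- intersect(keep_cols, names(records))
  agg <- stats::aggregate(list(conc = conc),
                          by = list(sample_id = records$sample_id,
                                    amplicon = records$amplicon),
                          FUN = geometric_mean)
  out <- list()
  for (s in unique(agg$sample_id)) {
    rows <- agg[agg$sample_id == s, , drop = FALSE]
    refs <- rows$conc[rows$amplicon %in% reference_amplicons]
    if (!length(refs))
      stopf("sample '%s' has no reference amplicon measurement", s)
    tgt <- rows[!(rows$amplicon %in% reference_amplicons), , drop = FALSE]
    if (!nrow(tgt)) next
    meta <- records[match(s, records$sample_id), keep_cols, drop = FALSE]
    out[[s]] <- data.frame(meta, sample_id = s, gene = tgt$amplicon,
                           value_au = vapply(tgt$conc, normalize_to_references,
                                             numeric(1), reference_concs = refs),
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Calibrate a normalized expression table to a control sample
#'
#' Divides `value_au` by the control sample's value, per gene, so that the
#' control sample is exactly 1 in every calibrated series.
#'
#' @param expression Normalized expression table with columns `sample_id`,
#'   `gene`, `value_au`.
#' @param control_sample_id Sample id of the shared control.
#' @return The table with calibrated `value_au`.
#' @export
calibrate_expression <- function(expression, control_sample_id) {
  assert_columns(expression, c("sample_id", "gene", "value_au"),
                 "expression table")
  for (g in unique(expression$gene)) {
    rows <- expression$gene == g
    vals <- setNames(expression$value_au[rows], expression$sample_id[rows])
    if (!control_sample_id %in% names(vals))
      stopf("control sample '%s' not measured for gene '%s'",
            control_sample_id, g)
    expression$value_au[rows] <- calibrate_to_control(vals, control_sample_id)
  }
  expression
}
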