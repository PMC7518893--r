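read_table_arg <- function(x, what) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) {
    if (!file.exists(x)) stopf("%s file not found: %s", what, x)
    return(read.csv(x, stringsAsFactors = FALSE))
  }
  if (!is.data.frame(x)) stopf("%s must be a data frame or CSV path", what)
  x
}

validate_schema <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stopf("%s: missing column(s) %s", what, paste(missing, collapse = ", "))
  for (cl in cols) {
    bad <- which(is.na(df[[cl]]))
    if (cl %in% c("day", "value_au", "transfer_day") && length(bad))
      stopf("%s: NA in column '%s' at row(s) %s", what, cl,
            paste(utils::head(bad, 5), collapse = ", "))
  }
  invisible(df)
}

write_output_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end-to-end on tidy input tables: breakpoint
#' detection, decay-feature extraction, starting-level and slope
#' comparisons against the control genotype, the variability (CV) report,
#' post-vern fits, and the fitness models. Stages whose inputs are missing
#' are skipped with a logged reason. All outputs are written as CSV/JSON to
#' `output_dir` together with a provenance manifest (package version,
#' parameter hash, seeds, per-stage log); reruns with identical inputs and
#' parameters produce byte-identical files.
#'
#' @param expression Normalized expression table (data frame or CSV path)
#'   with columns genotype, day, block, replicate, gene, value_au (site and
#'   year optional).
#' @param bolting Optional transfer table (see [postvern_from_transfers()]).
#' @param fitness Optional plant-level fitness table (see
#'   [fitness_summaries()]).
#' @param output_dir Directory for outputs (created if needed).
#' @param control_genotype Reference genotype for comparisons.
#' @param gene Target gene analysed (default `"FLC_spliced"`).
#' @param induction_gene Gene used for breakpoint detection.
#' @param breakpoint `"auto"` (detect from the control genotype's
#'   `induction_gene` series) or a fixed day.
#' @param mode,scale,exclude_after_day Passed to [extract_features()].
#' @param alpha Significance level for Dunnett comparisons.
#' @param q False discovery rate for the variability report.
#' @param seed Seed for the Dunnett Monte-Carlo adjustment.
#' @return (Invisibly) a list with the stage results (`breakpoint`,
#'   `features`, `starting_dunnett`, `slope_contrasts`, `variability`,
#'   `postvern`, `fitness`) and the `manifest`.
#' @export
run_pipeline <- function(expression, bolting = NULL, fitness = NULL,
                         output_dir, control_genotype = "Col FRI",
                         gene = "FLC_spliced", induction_gene = "VIN3",
                         breakpoint = "auto",
                         mode = c("two_phase", "combined"),
                         scale = c("linear", "log"),
                         exclude_after_day = NULL, alpha = 0.05, q = 0.05,
                         seed = 1) {
  mode <- match.arg(mode)
  scale <- match.arg(scale)
  expression <- read_table_arg(expression, "expression")
  bolting <- read_table_arg(bolting, "bolting")
  fitness <- read_table_arg(fitness, "fitness")
  validate_schema(expression, c("genotype", "day", "block", "replicate",
                                "gene", "value_au"), "expression table")
  if (!control_genotype %in% expression$genotype)
    stopf("control genotype '%s' not present in expression data",
          control_genotype)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  note <- function(stage, status, detail = "") {
    log[[length(log) + 1]] <<- data.frame(stage = stage, status = status,
                                          detail = detail,
                                          stringsAsFactors = FALSE)
  }

  ## breakpoint
  bp_est <- NULL
  if (identical(breakpoint, "auto")) {
    vin3 <- expression[expression$gene == induction_gene &
                         expression$genotype == control_genotype, ,
                       drop = FALSE]
    if (!nrow(vin3))
      stopf("breakpoint = 'auto' but no '%s' records for genotype '%s'",
            induction_gene, control_genotype)
    bp_est <- detect_induction(vin3)
    if (!bp_est$detected && mode == "two_phase")
      stopf("no VIN3 induction detected; supply a fixed breakpoint or use combined mode")
    bp_day <- bp_est$day
    note("breakpoint", "ok", sprintf("detected day %g", bp_day))
  } else {
    bp_day <- resolve_breakpoint(breakpoint)
    note("breakpoint", "ok", sprintf("fixed day %g", bp_day))
  }

  ## decay features
  features <- extract_features(expression, breakpoint = bp_day, mode = mode,
                               scale = scale,
                               exclude_after_day = exclude_after_day,
                               gene = gene)
  write_output_csv(features, output_dir, "features.csv")
  note("fit-decay", "ok", sprintf("%d genotypes", nrow(features)))

  ## comparisons vs control
  flc <- expression[expression$gene == gene, , drop = FALSE]
  day1 <- min(flc$day)
  first <- flc[flc$day == day1, , drop = FALSE]
  starting_dunnett <- dunnett_vs_control(first$value_au, first$genotype,
                                         control_genotype, alpha = alpha,
                                         seed = seed)
  write_output_csv(as.data.frame(starting_dunnett), output_dir,
                   "starting_level_comparisons.csv")
  slope_contrasts <- list()
  if (mode == "two_phase") {
    windows <- list(vindep = flc[flc$day <= bp_day, , drop = FALSE],
                    vdep = flc[flc$day > bp_day, , drop = FALSE])
  } else {
    keep <- if (is.null(exclude_after_day)) flc else
      flc[flc$day <= exclude_after_day, , drop = FALSE]
    windows <- list(combined = keep)
  }
  for (w in names(windows)) {
    sub <- windows[[w]]
    if (length(unique(sub$day)) < 2) {
      note(sprintf("compare-%s", w), "skipped", "fewer than 2 days in window")
      next
    }
    slope_contrasts[[w]] <- mixed_slope_contrasts(sub, control_genotype)
    out <- slope_contrasts[[w]]$contrasts
    out$window <- w
    write_output_csv(out, output_dir, sprintf("slope_contrasts_%s.csv", w))
    note(sprintf("compare-%s", w), "ok",
         sprintf("%d contrasts (%s)", nrow(out), slope_contrasts[[w]]$method))
  }

  ## variability
  variability <- variability_report(features, q = q)
  write_output_csv(variability$cv, output_dir, "variability_cv.csv")
  write_output_csv(variability$tests, output_dir, "variability_tests.csv")
  note("variability", "ok", sprintf("%d tests", nrow(variability$tests)))

  ## postvern
  postvern <- NULL
  if (!is.null(bolting)) {
    validate_schema(bolting, c("genotype", "transfer_day", "days_to_bolting"),
                    "bolting table")
    postvern <- postvern_from_transfers(bolting)
    ptab <- do.call(rbind, lapply(postvern, function(f)
      data.frame(genotype = f$genotype, m = f$m, c = f$c, se_m = f$se_m,
                 p_m = f$p_m, n_points = f$n_points, reliable = f$reliable,
                 n_excluded = f$n_excluded, reason = f$reason %||% NA,
                 stringsAsFactors = FALSE)))
    rownames(ptab) <- NULL
    write_output_csv(ptab, output_dir, "postvern.csv")
    note("postvern", "ok", sprintf("%d genotypes", length(postvern)))
  } else {
    note("postvern", "skipped", "no bolting table")
  }

  ## fitness
  fitness_results <- NULL
  if (!is.null(fitness)) {
    validate_schema(fitness, c("genotype", "bolted_before_winter",
                               "survived", "rosette_branches", "siliques"),
                    "fitness table")
    pv <- if (!is.null(postvern))
      vapply(postvern, `[[`, numeric(1), "m") else NULL
    summaries <- fitness_summaries(fitness, postvern = pv)
    write_output_csv(summaries, output_dir, "fitness_summary.csv")
    precocious <- tryCatch(precocious_bolting_model(fitness),
                           error = function(e) NULL)
    surv_test <- {
      b <- fitness[fitness$bolted_before_winter, , drop = FALSE]
      nb <- fitness[!fitness$bolted_before_winter, , drop = FALSE]
      if (nrow(b) && nrow(nb))
        survival_proportion_test(c(sum(b$survived), nrow(b)),
                                 c(sum(nb$survived), nrow(nb)))
      else NULL
    }
    sil <- if (!is.null(pv) && sum(stats::complete.cases(
      summaries[, c("postvern_m", "pct_survival", "total_siliques")])) >= 4)
      silique_models(summaries, plants = fitness) else NULL
    rank_res <- {
      surv <- fitness[fitness$survived, , drop = FALSE]
      a <- surv$siliques[surv$bolted_before_winter]
      b2 <- surv$siliques[!surv$bolted_before_winter]
      if (length(a) && length(b2)) rank_test(a, b2) else NULL
    }
    fitness_results <- list(summaries = summaries, precocious = precocious,
                            survival_test = surv_test,
                            silique_models = sil, rank_test = rank_res)
    models_json <- list(
      precocious = if (!is.null(precocious)) list(
        glm_slope = precocious$glm_slope, glm_p = precocious$glm_p,
        separation = precocious$separation,
        r_squared = precocious$r_squared, lm_p = precocious$lm_p),
      survival_test = surv_test,
      silique_total = if (!is.null(sil)) list(
        coefficients = as.list(coef(sil$total_model)),
        r_squared = sil$total_r_squared,
        adj_r_squared = sil$total_adj_r_squared),
      rank_test = if (!is.null(rank_res)) list(
        U = rank_res$U, p_value = rank_res$p_value, exact = rank_res$exact))
    jsonlite::write_json(models_json, file.path(output_dir,
                                                "fitness_models.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    note("fitness", "ok", sprintf("%d genotypes", nrow(summaries)))
  } else {
    note("fitness", "skipped", "no fitness table")
  }

  ## manifest
  params <- list(control_genotype = control_genotype, gene = gene,
                 induction_gene = induction_gene,
                 breakpoint = if (identical(breakpoint, "auto")) "auto"
                 else bp_day,
                 breakpoint_day = bp_day, mode = mode, scale = scale,
                 exclude_after_day = exclude_after_day, alpha = alpha,
                 q = q, seed = seed)
  cfg_path <- file.path(output_dir, "params.json")
  jsonlite::write_json(params, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  manifest <- list(package = "vernadyn",
                   version = as.character(packageVersion("vernadyn")),
                   params_md5 = unname(tools::md5sum(cfg_path)),
                   seed = seed,
                   n_expression_rows = nrow(expression),
                   stages = do.call(rbind, log))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null")
  invisible(list(breakpoint = bp_est %||% bp_day, features = features,
                 starting_dunnett = starting_dunnett,
                 slope_contrasts = slope_contrasts,
                 variability = variability, postvern = postvern,
                 fitness = fitness_results, manifest = manifest))
}

#' Run the pipeline from a YAML configuration file
#'
#' Reads a YAML file whose keys are the arguments of [run_pipeline()]
#' (table arguments given as CSV paths, resolved relative to the YAML
#' file's directory) and runs the pipeline.
#'
#' @param path Path to the YAML configuration.
#' @return See [run_pipeline()].
#' @export
run_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("expression", "bolting", "fitness")) {
    if (!is.null(cfg[[key]]) && is.character(cfg[[key]]) &&
        !file.exists(cfg[[key]]))
      cfg[[key]] <- file.path(base, cfg[[key]])
  }
  if (!is.null(cfg$output_dir) && !grepl("^/", cfg$output_dir))
    cfg$output_dir <- file.path(base, cfg$output_dir)
  do.call(run_pipeline, cfg)
}
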