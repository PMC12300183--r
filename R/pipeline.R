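# End-to-end orchestration: simulate or read data, run the redox and
# abundance analyses, enrichment statistics, and write the report bundle.

#' Pipeline configuration
#'
#' @param mode "all" (simulate then run everything), "simulate" (write
#'   simulated tables only), or "redox"/"abundance"/"enrich" on user data.
#' @param out_dir output directory for the report bundle.
#' @param sim a [sim_config()] governing the simulated dataset.
#' @param redox_psms,redox_design,abundance_psms,abundance_design,annotations
#'   input TSV paths for the non-simulate modes; designs are TSV versions
#'   of the channel-design table.
#' @param group_map optional TSV path (protein_id, group_id) of rows to
#'   merge before abundance analysis; for simulated data the truth's merge
#'   keys are used instead.
#' @param min_reps replicate-presence filter threshold for the redox table.
#' @param ratio_threshold,missing_frac channel QC thresholds, see
#'   [qc_channels()].
#' @param s0,target_fdr,n_perm significance parameters, see
#'   [differential_abundance()].
#' @param center "mean" or "median" channel centering.
#' @param seed single seed governing every stochastic stage.
#' @param force overwrite existing output files.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("all", "simulate", "redox",
                                     "abundance", "enrich"),
                            out_dir = tempfile("redoxtmt_run_"),
                            sim = sim_config(),
                            redox_psms = NULL, redox_design = NULL,
                            abundance_psms = NULL, abundance_design = NULL,
                            annotations = NULL, group_map = NULL,
                            min_reps = 3,
                            ratio_threshold = 100, missing_frac = 0.5,
                            s0 = 1, target_fdr = 0.02, n_perm = 250,
                            center = "mean",
                            seed = 1L, force = FALSE) {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, out_dir = out_dir, sim = sim,
              redox_psms = redox_psms, redox_design = redox_design,
              abundance_psms = abundance_psms,
              abundance_design = abundance_design,
              annotations = annotations, group_map = group_map,
              min_reps = min_reps, ratio_threshold = ratio_threshold,
              missing_frac = missing_frac, s0 = s0,
              target_fdr = target_fdr, n_perm = n_perm,
              center = match.arg(center, c("mean", "median")),
              seed = as.integer(seed), force = isTRUE(force))
  if (target_fdr <= 0 || target_fdr >= 1) stopf("target_fdr must be in (0, 1)")
  needed <- switch(mode,
                   redox = c("redox_psms", "redox_design"),
                   abundance = c("abundance_psms", "abundance_design"),
                   enrich = c("abundance_psms", "abundance_design", "annotations"),
                   character(0))
  for (fld in needed) {
    if (is.null(cfg[[fld]])) stopf("mode '%s' requires '%s'", mode, fld)
    if (!file.exists(cfg[[fld]])) stopf("input file not found: %s", cfg[[fld]])
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' @noRd
read_design_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  d$channel_id <- as.character(d$channel_id)
  if ("replicate" %in% names(d)) d$replicate <- as.integer(d$replicate)
  validate_channel_design(d)
  d
}

#' Run the configured analysis end to end
#'
#' Stage order: simulate (or load) -> PSM roll-up -> redox stoichiometry
#' and strain comparison (reported on the full table and again after the
#' replicate-presence filter) -> abundance QC/scaling/normalization ->
#' S0 permutation-FDR significance -> hierarchical clustering ->
#' enrichment statistics.  All result tables are written as TSV, a
#' machine-readable `summary.json` captures the headline statistics, and
#' `run.log` records stage timings and filter counts.  Any stage error
#' aborts with the stage name attached.
#'
#' @param config a [pipeline_config()].
#' @return the report bundle (named list), invisibly; elements include
#'   `summary`, `redox`, `abundance`, `enrichment`, `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  log_msg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    log_lines <<- c(log_lines, line)
  }
  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    log_msg("stage '%s' done in %.2f s", name, proc.time()[["elapsed"]] - t0)
    res
  }

  mode <- config$mode
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tables <- list()
  summary <- list(seed = config$seed, mode = mode)
  report <- list(config = config)

  truth <- NULL; catalog <- NULL
  iodo <- NULL; tmt <- NULL
  group_map <- NULL

  if (mode %in% c("all", "simulate")) {
    sim <- run_stage("simulate", {
      truth <- simulate_ground_truth(config$sim)
      list(truth = truth,
           iodo = simulate_iodotmt_psms(truth, config$sim),
           tmt = simulate_tmt_psms(truth, config$sim))
    })
    truth <- sim$truth; iodo <- sim$iodo; tmt <- sim$tmt
    catalog <- truth_annotations(truth)
    group_map <- truth_group_map(truth)
    log_msg("simulated %d proteins (seed %d)", nrow(truth), config$sim$seed)
    if (mode == "simulate") {
      tables <- list(sim_truth = truth,
                     iodotmt_psms = iodo$psms,
                     iodotmt_design = iodo$design,
                     tmt_psms = tmt$psms,
                     tmt_design = tmt$design)
      paths <- write_results(tables, out_dir, force = config$force)
      writeLines(log_lines, file.path(out_dir, "run.log"))
      return(invisible(list(truth = truth, paths = paths)))
    }
  }

  if (mode == "redox") {
    design <- read_design_tsv(config$redox_design)
    iodo <- list(psms = read_psm_table(config$redox_psms, design),
                 design = design)
  }
  if (mode %in% c("abundance", "enrich")) {
    design <- read_design_tsv(config$abundance_design)
    tmt <- list(psms = read_psm_table(config$abundance_psms, design),
                design = design)
    if (!is.null(config$annotations))
      catalog <- read_annotations(config$annotations)
    if (!is.null(config$group_map)) {
      gm <- utils::read.delim(config$group_map, stringsAsFactors = FALSE)
      group_map <- stats::setNames(gm$group_id, gm$protein_id)
    }
  }

  # ---- redox branch -------------------------------------------------
  if (!is.null(iodo)) {
    redox <- run_stage("redox", {
      mat <- aggregate_psms(iodo$psms, iodo$design)
      rt <- compute_stoichiometry(mat, iodo$design)
      cmp_all <- redox_comparison(rt)
      rt_f <- filter_by_replicate_presence(rt, config$min_reps)
      cmp_f <- redox_comparison(rt_f)
      corr <- replicate_correlation(rt)
      list(matrix = mat, all = cmp_all, filtered = cmp_f, correlation = corr)
    })
    report$redox <- redox
    tables$redox_stoichiometry <- redox$all$table
    tables$redox_stoichiometry_filtered <- redox$filtered$table
    tables$redox_histogram <- redox$all$fc_hist
    tables$correlation_matrix <- redox$correlation$r
    tables$redox_volcano <- with(redox$all$table, data.frame(
      protein_id = protein_id, log2_fc = log2(fc),
      neg_log10_p = -log10(p), stringsAsFactors = FALSE))
    summary$redox <- list(
      n_proteins = nrow(redox$all$table),
      n_min_reps = nrow(redox$filtered$table),
      min_reps = config$min_reps,
      all = list(strain_summary = redox$all$strain_summary,
                 fc = redox$all$fc_summary,
                 global_paired_t = redox$all$global[c("n", "t", "df", "p_label", "note")]),
      filtered = list(strain_summary = redox$filtered$strain_summary,
                      fc = redox$filtered$fc_summary,
                      global_paired_t = redox$filtered$global[c("n", "t", "df", "p_label", "note")]),
      correlation_range = range(redox$correlation$r[upper.tri(redox$correlation$r)],
                                na.rm = TRUE))
    log_msg("redox: %d proteins, %d with >= %d replicates per strain",
            nrow(redox$all$table), nrow(redox$filtered$table), config$min_reps)
  }

  # ---- abundance branch ---------------------------------------------
  da <- NULL; norm <- NULL; design_a <- NULL
  if (!is.null(tmt)) {
    abundance <- run_stage("abundance", {
      design_a <- tmt$design
      mat <- aggregate_psms(tmt$psms, design_a)
      n_before <- nrow(mat)
      if (!is.null(group_map) && length(group_map) > 0)
        mat <- merge_protein_groups(mat, group_map)
      qc <- qc_channels(mat, config$ratio_threshold, config$missing_frac)
      scaled <- scale_channels(qc$kept)
      norm <- log2_and_center(scaled, center = config$center)
      keep_design <- design_a[design_a$channel_id %in% colnames(norm), ]
      groups <- list(
        HT = keep_design$channel_id[keep_design$strain == "HT" &
                                      keep_design$role == "abundance"],
        LT = keep_design$channel_id[keep_design$strain == "LT" &
                                      keep_design$role == "abundance"])
      da <- differential_abundance(norm, groups, s0 = config$s0,
                                   target_fdr = config$target_fdr,
                                   n_perm = config$n_perm,
                                   seed = config$seed)
      cl <- hierarchical_cluster(norm[, c(groups$HT, groups$LT), drop = FALSE])
      list(matrix = mat, n_before_merge = n_before, qc = qc,
           normalized = norm, groups = groups, da = da, cluster = cl)
    })
    report$abundance <- abundance
    da <- abundance$da; norm <- abundance$normalized
    tables$abundance_results <- da$table
    tables$abundance_qc <- abundance$qc$report
    tables$abundance_fdr_curve <- da$fdr_curve
    tables$volcano <- with(da$table, data.frame(
      protein_id = protein_id, diff = diff, neg_log10_p = -log10(p),
      significant = significant, stringsAsFactors = FALSE))
    tables$cluster_columns <- data.frame(
      channel = names(abundance$cluster$partition),
      cluster = unname(abundance$cluster$partition),
      order = order(abundance$cluster$col_order),
      stringsAsFactors = FALSE)
    if (length(abundance$qc$dropped))
      log_msg("dropped channel(s): %s", paste(abundance$qc$dropped, collapse = ", "))
    log_msg("abundance: %d proteins quantified, %d tested, %d significant (FDR %.3g, S0 %.3g)",
            nrow(da$table), nrow(da$table) - da$n_excluded,
            sum(da$table$significant), config$target_fdr, config$s0)
    summary$abundance <- list(
      n_proteins_before_merge = abundance$n_before_merge,
      n_proteins = nrow(da$table),
      n_tested = nrow(da$table) - da$n_excluded,
      channels_dropped = abundance$qc$dropped,
      n_dap = sum(da$table$significant),
      n_dap_up = sum(da$table$significant & da$table$diff > 0),
      d_threshold = da$d_threshold,
      s0 = config$s0, target_fdr = config$target_fdr,
      n_perm_used = da$n_perm_used,
      cluster_partition = as.list(abundance$cluster$partition))
  }

  # ---- enrichment branch --------------------------------------------
  if (!is.null(da) && !is.null(catalog)) {
    enr <- run_stage("enrichment", {
      flags <- stats::setNames(da$table$significant, da$table$protein_id)
      fish <- fisher_enrichment(flags, catalog, universe = "annotated")
      sample_cols <- c(report$abundance$groups$HT, report$abundance$groups$LT)
      oned_samples <- one_d_annotation_enrichment(
        norm[, sample_cols, drop = FALSE], catalog)
      fc_vals <- stats::setNames(da$table$diff, da$table$protein_id)
      oned_fc <- one_d_annotation_enrichment(fc_vals, catalog)
      oned_fc$sample <- "log2_fc"
      list(fisher = fish, oned = rbind(oned_samples, oned_fc))
    })
    report$enrichment <- enr
    tables$fisher_enrichment <- enr$fisher
    tables$one_d_enrichment <- enr$oned
    summary$enrichment <- list(
      fisher = enr$fisher,
      n_terms_significant = sum(enr$fisher$q <= config$target_fdr),
      oned_terms_significant = unique(enr$oned$term[enr$oned$q <= config$target_fdr]))
    log_msg("enrichment: %d terms tested by Fisher, %d significant at FDR %.3g",
            nrow(enr$fisher), sum(enr$fisher$q <= config$target_fdr),
            config$target_fdr)
  }

  paths <- run_stage("write", {
    p <- write_results(tables, out_dir, force = config$force)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         pretty = TRUE, na = "null", force = TRUE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
    c(p, summary = file.path(out_dir, "summary.json"),
      log = file.path(out_dir, "run.log"))
  })
  report$summary <- summary
  report$paths <- paths
  report$truth <- truth
  class(report) <- "pipeline_report"
  invisible(report)
}
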