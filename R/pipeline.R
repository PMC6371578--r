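#' Pipeline configuration
#'
#' Collects the thresholds and paths the staged pipeline uses.  Defaults are
#' the analysis defaults used throughout the package: BH alpha 0.05, minimum
#' absolute log2FC 0.1, delta-beta decile cuts at the 0.1/0.8 quantiles,
#' dominant-region tolerance 0.005, moderated fits, 500-tree forests.
#'
#' @param input_dir Directory with the cohort TSV file set (see
#'   [write_cohort()]); for the `simulate` stage it is the output directory.
#' @param out_dir Directory where stage outputs are written.
#' @param alpha,min_abs_lfc,decile_low,decile_high,dominant_tolerance,
#'   moderated,n_trees Analysis parameters.
#' @param max_k Largest panel size searched by the classifier stage.
#' @param regions Region selectors for the per-region methylation stage.
#' @param sim Optional list of [sim_config()] overrides for `simulate`.
#' @param seed Master seed.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL, out_dir = "methylexpr-out",
                            alpha = 0.05, min_abs_lfc = 0.1,
                            decile_low = 0.1, decile_high = 0.8,
                            dominant_tolerance = 0.005, moderated = TRUE,
                            n_trees = 500, max_k = 30,
                            regions = REGION_LABELS, sim = list(), seed = 1) {
  cfg <- list(input_dir = input_dir, out_dir = out_dir, alpha = alpha,
              min_abs_lfc = min_abs_lfc, decile_low = decile_low,
              decile_high = decile_high,
              dominant_tolerance = dominant_tolerance, moderated = moderated,
              n_trees = n_trees, max_k = max_k, regions = regions, sim = sim,
              seed = seed)
  num_in <- function(f, lo, hi) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < lo || v > hi)
      stop("invalid config: '", f, "' must be in [", lo, ", ", hi, "]",
           call. = FALSE)
  }
  num_in("alpha", 0, 1); num_in("min_abs_lfc", 0, Inf)
  num_in("decile_low", 0, 1); num_in("decile_high", 0, 1)
  num_in("dominant_tolerance", 0, 1)
  num_in("n_trees", 1, Inf); num_in("max_k", 1, Inf)
  if (cfg$decile_low >= cfg$decile_high)
    stop("invalid config: decile_low must be below decile_high", call. = FALSE)
  if (!all(cfg$regions %in% REGION_LABELS))
    stop("invalid config: unknown region selector", call. = FALSE)
  if (is.null(cfg$seed) || !is.numeric(cfg$seed))
    stop("invalid config: 'seed' must be set", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML document is a flat mapping of [pipeline_config()] fields (with
#' an optional nested `sim` mapping of [sim_config()] overrides); fields are
#' type- and range-checked, unknown fields rejected.
#'
#' @param path YAML file.
#' @param overrides Named list of values overriding the file (CLI flags).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config file must be a YAML mapping", call. = FALSE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("invalid config: unknown field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  raw[names(overrides)] <- overrides
  do.call(pipeline_config, raw)
}

.stage_names <- c("simulate", "diffexpr", "diffmeth", "intergenic",
                  "integrate", "classify", "full")

.manifest <- function(config, stage, outputs, counts) {
  cfgfile <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(config), cfgfile, auto_unbox = TRUE, digits = NA,
                       null = "null")
  list(stage = stage,
       config = unclass(config)[setdiff(names(config), "input_dir")],
       config_hash = unname(tools::md5sum(cfgfile)),
       seed = config$seed,
       r_version = as.character(getRversion()),
       package_version = as.character(utils::packageVersion("methylexpr")),
       outputs = outputs, row_counts = counts)
}

.load_inputs <- function(config) {
  if (is.null(config$input_dir))
    stop("missing inputs: 'input_dir' is not set", call. = FALSE)
  read_cohort(config$input_dir)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (write a synthetic cohort), `diffexpr` (DEG calling),
#' `diffmeth` (per-region and ALL-region DMG calling), `intergenic`
#' (differential intergenic CpGs + enhancer enrichment), `integrate`
#' (overlap classes, dominant regions, expression-methylation correlation),
#' `classify` (importance-ranked LOOCV panel), `full` (all of the above in
#' order on one cohort).  Each stage writes TSV outputs plus a JSON run
#' manifest (config hash, seed, versions, row counts) into `out_dir`.
#'
#' @param stage One of the stage names above.
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of the stage's in-memory results.
#' @export
run_stage <- function(stage, config) {
  if (!is.character(stage) || length(stage) != 1 || !(stage %in% .stage_names))
    stop("unknown stage '", paste(stage, collapse = ","),
         "'; expected one of: ", paste(.stage_names, collapse = ", "),
         call. = FALSE)
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  fp <- function(f) file.path(config$out_dir, f)
  outputs <- character(0); counts <- list(); results <- list()

  if (stage %in% c("simulate", "full")) {
    sim <- do.call(sim_config, c(config$sim,
                                 if (!("seed" %in% names(config$sim)))
                                   list(seed = config$seed)))
    cohort <- generate_cohort(sim)
    dir_out <- if (stage == "simulate" && !is.null(config$input_dir))
      config$input_dir else fp("cohort")
    write_cohort(cohort, dir_out)
    outputs <- c(outputs, dir_out)
    counts$genes <- nrow(cohort$expression$values)
    counts$probes <- nrow(cohort$methylation$values)
    results$cohort <- cohort
  }

  if (stage %in% c("diffexpr", "diffmeth", "intergenic", "integrate", "classify", "full")) {
    cohort <- if (!is.null(results$cohort)) results$cohort else .load_inputs(config)
  }

  if (stage %in% c("diffexpr", "integrate", "classify", "full")) {
    es <- fit_group_model(cohort$expression, moderated = config$moderated)
    degs <- call_degs(es, alpha = config$alpha, min_abs_lfc = config$min_abs_lfc)
    results$degs <- degs
    if (stage %in% c("diffexpr", "full")) {
      write_table(degs, fp("degs.tsv"))
      outputs <- c(outputs, fp("degs.tsv")); counts$degs <- sum(degs$significant)
    }
  }

  if (stage %in% c("diffmeth", "integrate", "classify", "full")) {
    levels <- stats::setNames(
      lapply(c(config$regions, "ALL"), function(rg)
        aggregate_region(cohort$methylation, cohort$annotation, rg)),
      c(config$regions, "ALL"))
    results$region_levels <- levels
    dmg_tables <- lapply(levels, function(lv) {
      deltas <- delta_beta(lv)
      ms <- fit_group_model(region_m_values(lv), moderated = config$moderated)
      call_dmfs(ms, deltas,
                decile_thresholds(deltas, c(config$decile_low, config$decile_high)),
                alpha = config$alpha)
    })
    results$dmgs <- dmg_tables
    if (stage %in% c("diffmeth", "full")) {
      for (rg in names(dmg_tables)) {
        f <- fp(sprintf("dmgs_%s.tsv", rg))
        write_table(dmg_tables[[rg]], f)
        outputs <- c(outputs, f)
        counts[[paste0("dmgs_", rg)]] <- sum(dmg_tables[[rg]]$significant)
      }
    }
  }

  if (stage %in% c("intergenic", "full")) {
    ig_ids <- cohort$annotation$probes$probe_id[cohort$annotation$probes$intergenic]
    ig_ids <- intersect(ig_ids, rownames(cohort$methylation$values))
    if (length(ig_ids) > 0) {
      ig <- labeled_matrix(cohort$methylation$values[ig_ids, , drop = FALSE],
                           "beta", as.character(cohort$methylation$group),
                           cohort$methylation$gender)
      deltas <- delta_beta(ig)
      ms <- fit_group_model(as_m_values(ig), moderated = config$moderated)
      dmcs <- call_dmfs(ms, deltas,
                        decile_thresholds(deltas, c(config$decile_low, config$decile_high)),
                        alpha = config$alpha)
      enr <- enhancer_enrichment(dmcs, cohort$annotation)
      write_table(dmcs, fp("intergenic_dmcs.tsv"))
      enr_df <- data.frame(group = rownames(enr$table),
                           enhancer = enr$table[, 1], non_enhancer = enr$table[, 2],
                           chisq = enr$statistic, p_value = enr$p_value)
      write_table(enr_df, fp("enhancer_enrichment.tsv"))
      outputs <- c(outputs, fp("intergenic_dmcs.tsv"), fp("enhancer_enrichment.tsv"))
      counts$intergenic_dmcs <- sum(dmcs$significant)
      results$intergenic <- dmcs; results$enrichment <- enr
    }
  }

  if (stage %in% c("integrate", "full")) {
    overlap <- classify_overlap(results$degs, results$dmgs[["ALL"]])
    write_table(overlap, fp("overlap_classes.tsv"))
    hypo_up <- overlap$gene_id[overlap$overlap_class == "hypo-up"]
    dom <- dominant_region_table(results$region_levels, genes = hypo_up,
                                 tolerance = config$dominant_tolerance)
    write_table(dom, fp("dominant_regions.tsv"))
    n_cor <- min(sum(cohort$expression$group == "case"),
                 sum(cohort$expression$group == "control"))
    corr <- expr_meth_correlation(cohort$expression, results$region_levels,
                                  hypo_up, n_per_group = n_cor,
                                  seed = config$seed)
    write_table(corr, fp("expr_meth_correlation.tsv"))
    outputs <- c(outputs, fp("overlap_classes.tsv"), fp("dominant_regions.tsv"),
                 fp("expr_meth_correlation.tsv"))
    counts$overlap <- nrow(overlap); counts$hypo_up <- length(hypo_up)
    results$overlap <- overlap; results$dominant <- dom; results$correlation <- corr
  }

  if (stage %in% c("classify", "full")) {
    if (is.null(results$overlap)) {
      overlap <- classify_overlap(results$degs, results$dmgs[["ALL"]])
      results$overlap <- overlap
    }
    hypo_up <- results$overlap$gene_id[results$overlap$overlap_class == "hypo-up"]
    if (length(hypo_up) == 0)
      stop("no hypo-up genes available for the classifier", call. = FALSE)
    ft <- feature_table(cohort$expression, hypo_up, "expression_log2")
    ranked <- rank_importance(ft, n_trees = config$n_trees, seed = config$seed)
    panel <- incremental_panel(ft, ranked$feature, n_trees = config$n_trees,
                               seed = config$seed, max_k = config$max_k)
    write_table(ranked, fp("importance_ranking.tsv"))
    write_table(data.frame(k = as.integer(names(panel$auc_by_k)),
                           auc = unname(panel$auc_by_k)), fp("auc_by_k.tsv"))
    write_table(data.frame(feature = panel$best_panel), fp("best_panel.tsv"))
    write_table(panel$roc_points, fp("roc_points.tsv"))
    outputs <- c(outputs, fp("importance_ranking.tsv"), fp("auc_by_k.tsv"),
                 fp("best_panel.tsv"), fp("roc_points.tsv"))
    counts$panel_size <- panel$best_k
    results$panel <- panel
  }

  manifest <- .manifest(config, stage, outputs, counts)
  jsonlite::write_json(manifest, fp(sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(results)
}
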