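#' Configuration for a synthetic paired expression + methylation cohort
#'
#' Defines a two-group (case/control) blood cohort with paired log2
#' expression and 450K-style beta-value methylation, planted differential
#' genes of four classes (hypo-up, hyper-down, hypo-down, hyper-up), planted
#' dominant methylation-altered regions, and planted differential intergenic
#' CpGs enriched for enhancer probes.
#'
#' Methylation effects are planted on the M-value (logit2) scale and
#' calibrated so the realized case-control mean beta difference of a dominant
#' region is approximately `meth_effect` in magnitude; this keeps beta values
#' bounded in (0,1) and matches the M-value testing downstream.  All probes
#' of a gene region share one baseline beta (with small per-probe jitter on
#' the M scale) so that region averaging is meaningful.
#'
#' @param n_case,n_control Samples per group.
#' @param n_genes Number of genes.
#' @param probes_per_region CpG probes per gene per region (0 allowed).
#' @param n_intergenic Number of intergenic CpG probes.
#' @param frac_enhancer_intergenic Baseline probability that an intergenic
#'   probe carries an enhancer flag.
#' @param n_hypo_up,n_hyper_down,n_hypo_down,n_hyper_up Planted gene counts
#'   per overlap class.
#' @param expr_effect Log2 mean expression shift (case - control) for planted
#'   genes; sign follows the class (up classes +, down classes -).
#' @param meth_effect Beta-scale shift magnitude of planted dominant regions
#'   (hypo classes shift down in cases, hyper classes up).
#' @param meth_offregion_effect Beta shift applied to the non-dominant regions
#'   of planted genes (default 0).
#' @param dominant_regions Planted dominant region labels: `NULL` (one region
#'   drawn at random per planted gene), a character vector applied to every
#'   planted gene, or a list with one character vector per planted gene.
#' @param n_diff_intergenic Planted differential intergenic CpGs (80% hypo,
#'   20% hyper).
#' @param enhancer_enrichment_odds Multiplier on the enhancer-flag odds of
#'   planted differential intergenic CpGs.
#' @param expr_noise_sd Per-observation Gaussian noise sd, log2 scale.
#' @param meth_noise_sd Per-observation Gaussian noise sd, M-value scale.
#' @param baseline_beta_range Interval within (0,1) from which gene-region
#'   baseline betas are drawn.
#' @param gender_effect Optional log2 expression shift applied to males for a
#'   random 5% of genes (0 disables).
#' @param seed Master seed; all sub-streams derive from it deterministically.
#' @param plant_seed Optional seed for the gene-level ("biology") stream:
#'   planted gene identities, dominant regions, baselines, probe annotation
#'   and enhancer flags.  Defaults to a value derived from `seed`.  Two
#'   configurations sharing `plant_seed` but differing in `seed` describe
#'   fresh patient draws from the same disease process, which is what
#'   cross-cohort validation of a classifier requires.
#'
#' @return A validated object of class `sim_config`.
#' @seealso [generate_cohort()]
#' @export
sim_config <- function(n_case = 200, n_control = 200, n_genes = 2000,
                       probes_per_region = 2, n_intergenic = 1000,
                       frac_enhancer_intergenic = 0.32,
                       n_hypo_up = 85, n_hyper_down = 0, n_hypo_down = 0,
                       n_hyper_up = 0,
                       expr_effect = 0.3, meth_effect = 0.05,
                       meth_offregion_effect = 0,
                       dominant_regions = NULL,
                       n_diff_intergenic = 100,
                       enhancer_enrichment_odds = 2.2,
                       expr_noise_sd = 1.0, meth_noise_sd = 0.5,
                       baseline_beta_range = c(0.2, 0.8),
                       gender_effect = 0, seed = 1, plant_seed = NULL) {
  cfg <- list(n_case = n_case, n_control = n_control, n_genes = n_genes,
              probes_per_region = probes_per_region, n_intergenic = n_intergenic,
              frac_enhancer_intergenic = frac_enhancer_intergenic,
              n_hypo_up = n_hypo_up, n_hyper_down = n_hyper_down,
              n_hypo_down = n_hypo_down, n_hyper_up = n_hyper_up,
              expr_effect = expr_effect, meth_effect = meth_effect,
              meth_offregion_effect = meth_offregion_effect,
              dominant_regions = dominant_regions,
              n_diff_intergenic = n_diff_intergenic,
              enhancer_enrichment_odds = enhancer_enrichment_odds,
              expr_noise_sd = expr_noise_sd, meth_noise_sd = meth_noise_sd,
              baseline_beta_range = baseline_beta_range,
              gender_effect = gender_effect, seed = seed,
              plant_seed = plant_seed)
  counts <- c("n_case", "n_control", "n_genes", "probes_per_region",
              "n_intergenic", "n_hypo_up", "n_hyper_down", "n_hypo_down",
              "n_hyper_up", "n_diff_intergenic")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v != round(v))
      stop("invalid configuration: '", f, "' must be a non-negative integer",
           call. = FALSE)
  }
  n_planted <- n_hypo_up + n_hyper_down + n_hypo_down + n_hyper_up
  if (n_planted > n_genes)
    stop("invalid configuration: planted gene counts exceed 'n_genes'", call. = FALSE)
  if (n_diff_intergenic > n_intergenic)
    stop("invalid configuration: 'n_diff_intergenic' exceeds 'n_intergenic'",
         call. = FALSE)
  if (!is.numeric(frac_enhancer_intergenic) || frac_enhancer_intergenic < 0 ||
      frac_enhancer_intergenic > 1)
    stop("invalid configuration: 'frac_enhancer_intergenic' must be in [0,1]",
         call. = FALSE)
  if (length(baseline_beta_range) != 2 || baseline_beta_range[1] <= 0 ||
      baseline_beta_range[2] >= 1 || diff(baseline_beta_range) < 0)
    stop("invalid configuration: 'baseline_beta_range' must be an interval within (0,1)",
         call. = FALSE)
  for (f in c("expr_noise_sd", "meth_noise_sd")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0)
      stop("invalid configuration: '", f, "' must be >= 0", call. = FALSE)
  }
  if (!is.null(dominant_regions)) {
    labs <- unlist(dominant_regions, use.names = FALSE)
    if (!all(labs %in% REGION_LABELS))
      stop("invalid configuration: 'dominant_regions' contains unknown region label",
           call. = FALSE)
    if (is.list(dominant_regions) && length(dominant_regions) != n_planted)
      stop("invalid configuration: 'dominant_regions' list must have one entry per planted gene",
           call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("invalid configuration: 'seed' must be a single integer", call. = FALSE)
  if (!is.null(plant_seed) &&
      (!is.numeric(plant_seed) || length(plant_seed) != 1 || is.na(plant_seed)))
    stop("invalid configuration: 'plant_seed' must be a single integer",
         call. = FALSE)
  cfg$n_planted <- n_planted
  structure(cfg, class = "sim_config")
}

# deterministic sub-seed derivation from the master seed
.sub_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

.clamp_beta <- function(b, eps = 1e-6) pmin(pmax(b, eps), 1 - eps)

#' Generate a synthetic paired cohort
#'
#' Draws a complete cohort from a [sim_config()]: log2 expression
#' (`baseline + class effect + gender term + noise`), beta methylation
#' (gene-region baselines, planted M-scale shifts calibrated to the
#' beta-scale `meth_effect`, M-scale noise, back-transform), a
#' manifest-style probe annotation, sample metadata, and ground-truth tables.
#' Identical configurations (including seed) give bit-identical cohorts.
#'
#' @param config A [sim_config()].
#' @return An object of class `synthetic_cohort`: list with elements
#'   `expression` and `methylation` ([labeled_matrix()]), `annotation`
#'   ([probe_annotation()]), `metadata` (data frame `sample_id`, `group`,
#'   `gender`), `truth` (list: `genes` data frame with `feature_id`, `class`,
#'   `dominant_regions`; `intergenic` data frame with `probe_id`,
#'   `differential`, `direction`), and `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config"))
    config <- do.call(sim_config, config)
  cfg <- config
  seeds <- .sub_seeds(cfg$seed, 4)
  if (is.null(cfg$plant_seed)) cfg$plant_seed <- seeds[4]
  n <- cfg$n_case + cfg$n_control
  sample_ids <- sprintf("S%04d", seq_len(n))
  group <- c(rep("case", cfg$n_case), rep("control", cfg$n_control))
  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  ppr <- cfg$probes_per_region
  n_gene_probes <- cfg$n_genes * 6L * ppr

  ## -- gene-level ("biology") stream: everything that defines the disease
  ##    process and the array, independent of which patients were sampled
  set.seed(cfg$plant_seed)
  classes <- c(rep("hypo-up", cfg$n_hypo_up), rep("hyper-down", cfg$n_hyper_down),
               rep("hypo-down", cfg$n_hypo_down), rep("hyper-up", cfg$n_hyper_up))
  planted_idx <- if (cfg$n_planted > 0) sort(sample(cfg$n_genes, cfg$n_planted)) else integer(0)
  gene_class <- rep("none", cfg$n_genes)
  gene_class[planted_idx] <- classes
  dom <- vector("list", cfg$n_genes)
  if (cfg$n_planted > 0) {
    if (is.null(cfg$dominant_regions)) {
      dom[planted_idx] <- as.list(sample(REGION_LABELS, cfg$n_planted, replace = TRUE))
    } else if (is.list(cfg$dominant_regions)) {
      dom[planted_idx] <- cfg$dominant_regions
    } else {
      dom[planted_idx] <- rep(list(cfg$dominant_regions), cfg$n_planted)
    }
  }
  expr_base <- stats::runif(cfg$n_genes, 4, 10)
  gender_genes <- if (cfg$gender_effect != 0)
    sample(cfg$n_genes, max(1, round(0.05 * cfg$n_genes))) else integer(0)
  if (n_gene_probes > 0) {
    gene_of <- rep(seq_len(cfg$n_genes), each = 6L * ppr)
    region_of <- rep(rep(REGION_LABELS, each = ppr), times = cfg$n_genes)
    # shared baseline per gene-region, small per-probe jitter on the M scale
    base_region <- stats::runif(cfg$n_genes * 6L, cfg$baseline_beta_range[1],
                                cfg$baseline_beta_range[2])
    base_probe_m <- beta_to_m(rep(base_region, each = ppr)) +
      stats::rnorm(n_gene_probes, 0, 0.1)
  }
  if (cfg$n_intergenic > 0) {
    ig_diff <- rep(FALSE, cfg$n_intergenic)
    ig_diff[sample(cfg$n_intergenic, cfg$n_diff_intergenic)] <- TRUE
    ig_dir <- rep("none", cfg$n_intergenic)
    if (cfg$n_diff_intergenic > 0)
      ig_dir[ig_diff] <- sample(c("hypo", "hyper"), cfg$n_diff_intergenic,
                                replace = TRUE, prob = c(0.8, 0.2))
    p0 <- cfg$frac_enhancer_intergenic
    odds <- p0 / (1 - p0)
    p1 <- odds * cfg$enhancer_enrichment_odds /
      (1 + odds * cfg$enhancer_enrichment_odds)
    ig_enh <- stats::runif(cfg$n_intergenic) < ifelse(ig_diff, p1, p0)
    ig_base <- stats::runif(cfg$n_intergenic, cfg$baseline_beta_range[1],
                            cfg$baseline_beta_range[2])
  }
  n_probes <- n_gene_probes + cfg$n_intergenic
  probe_ids <- sprintf("cg%07d", seq_len(n_probes))
  ann_df <- data.frame(
    probe_id = probe_ids,
    chr = as.character(sample(1:22, n_probes, replace = TRUE)),
    position = sample.int(5e7, n_probes),
    gene_names = c(if (n_gene_probes > 0) gene_ids[gene_of],
                   rep("", cfg$n_intergenic)),
    region_groups = c(if (n_gene_probes > 0) region_of,
                      rep("", cfg$n_intergenic)),
    enhancer = c(rep(FALSE, n_gene_probes),
                 if (cfg$n_intergenic > 0) ig_enh),
    stringsAsFactors = FALSE)
  annotation <- probe_annotation(ann_df)

  ## -- metadata: gender 1:1 at random ---------------------------------------
  set.seed(seeds[1])
  gender <- sample(rep_len(c("male", "female"), n))
  metadata <- data.frame(sample_id = sample_ids, group = group,
                         gender = gender, stringsAsFactors = FALSE)
  case_ind <- as.numeric(group == "case")
  male_ind <- as.numeric(gender == "male")

  ## -- expression ------------------------------------------------------------
  set.seed(seeds[2])
  eff_sign <- c("hypo-up" = 1, "hyper-up" = 1, "hypo-down" = -1,
                "hyper-down" = -1, "none" = 0)
  expr_eff <- cfg$expr_effect * eff_sign[gene_class]
  gvec <- numeric(cfg$n_genes); gvec[gender_genes] <- cfg$gender_effect
  expr <- expr_base + outer(expr_eff, case_ind) + outer(gvec, male_ind) +
    matrix(stats::rnorm(cfg$n_genes * n, 0, cfg$expr_noise_sd), cfg$n_genes, n)
  dimnames(expr) <- list(gene_ids, sample_ids)

  ## -- methylation: gene-region probes --------------------------------------
  set.seed(seeds[3])
  meth_sign <- c("hypo-up" = -1, "hypo-down" = -1, "hyper-up" = 1,
                 "hyper-down" = 1, "none" = 0)
  if (n_gene_probes > 0) {
    base_probe_beta <- m_to_beta(base_probe_m)
    # planted shift: delta on the M scale reproducing the target beta shift
    shift <- numeric(n_gene_probes)
    is_dom <- mapply(function(g, r) !is.null(dom[[g]]) && r %in% dom[[g]],
                     gene_of, region_of)
    sgn <- meth_sign[gene_class[gene_of]]
    tgt <- ifelse(is_dom, cfg$meth_effect, cfg$meth_offregion_effect) * sgn
    nz <- tgt != 0
    if (any(nz)) {
      shifted_beta <- .clamp_beta(base_probe_beta[nz] + tgt[nz])
      shift[nz] <- beta_to_m(shifted_beta) - base_probe_m[nz]
    }
    m_gene <- base_probe_m + outer(shift, case_ind) +
      matrix(stats::rnorm(n_gene_probes * n, 0, cfg$meth_noise_sd), n_gene_probes, n)
  }

  ## -- intergenic probes -----------------------------------------------------
  if (cfg$n_intergenic > 0) {
    ig_base_m <- beta_to_m(ig_base)
    ig_tgt <- cfg$meth_effect * (ig_dir == "hyper") - cfg$meth_effect * (ig_dir == "hypo")
    ig_shift <- numeric(cfg$n_intergenic)
    nz <- ig_tgt != 0
    if (any(nz))
      ig_shift[nz] <- beta_to_m(.clamp_beta(ig_base[nz] + ig_tgt[nz])) - ig_base_m[nz]
    m_ig <- ig_base_m + outer(ig_shift, case_ind) +
      matrix(stats::rnorm(cfg$n_intergenic * n, 0, cfg$meth_noise_sd),
             cfg$n_intergenic, n)
  }

  m_all <- rbind(if (n_gene_probes > 0) m_gene,
                 if (cfg$n_intergenic > 0) m_ig)
  if (is.null(m_all)) m_all <- matrix(numeric(0), 0, n)
  beta <- .clamp_beta(m_to_beta(m_all))
  dim(beta) <- dim(m_all)
  dimnames(beta) <- list(probe_ids, sample_ids)

  ## -- truth -----------------------------------------------------------------
  truth_genes <- data.frame(
    feature_id = gene_ids,
    class = gene_class,
    dominant_regions = vapply(dom, function(d)
      if (is.null(d)) "" else paste(d, collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  truth_ig <- data.frame(
    probe_id = if (cfg$n_intergenic > 0) probe_ids[(n_gene_probes + 1):n_probes] else character(0),
    differential = if (cfg$n_intergenic > 0) ig_diff else logical(0),
    direction = if (cfg$n_intergenic > 0) ig_dir else character(0),
    stringsAsFactors = FALSE)

  structure(list(
    expression = labeled_matrix(expr, "log2_expression", group, gender),
    methylation = labeled_matrix(beta, "beta", group, gender),
    annotation = annotation,
    metadata = metadata,
    truth = list(genes = truth_genes, intergenic = truth_ig),
    config = cfg), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d case / %d control samples\n",
              x$config$n_case, x$config$n_control))
  cat(sprintf("  %d genes (%d planted), %d probes (%d intergenic)\n",
              x$config$n_genes, x$config$n_planted,
              nrow(x$methylation$values), x$config$n_intergenic))
  invisible(x)
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' Emits exactly the dialects the readers consume: `expression.tsv` and
#' `methylation.tsv` (matrix TSV, first column `ID`), `annotation.tsv`
#' (manifest-style), `metadata.tsv` (`sample_id`, `group`, `gender`), and the
#' ground-truth tables `truth_genes.tsv`, `truth_intergenic.tsv`.  Values
#' round-trip through [read_cohort()] to at least 1e-9.
#'
#' @param cohort A `synthetic_cohort`.
#' @param directory Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  if (!dir.exists(directory)) {
    ok <- tryCatch(dir.create(directory, recursive = TRUE), warning = function(w) FALSE)
    if (!isTRUE(ok)) stop("cannot create directory '", directory, "'", call. = FALSE)
  }
  wmat <- function(m, path) {
    df <- data.frame(ID = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    ok <- tryCatch({
      utils::write.table(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                         path, sep = "\t", quote = FALSE, row.names = FALSE)
      TRUE
    }, error = function(e) e, warning = function(w) w)
    if (!isTRUE(ok))
      stop("failed to write '", path, "': ", conditionMessage(ok), call. = FALSE)
  }
  fp <- function(f) file.path(directory, f)
  wmat(cohort$expression$values, fp("expression.tsv"))
  wmat(cohort$methylation$values, fp("methylation.tsv"))
  ann <- cohort$annotation
  adf <- ann$probes
  if (nrow(ann$assignments) > 0) {
    idx <- split(seq_len(nrow(ann$assignments)), ann$assignments$probe_id)
    gn <- vapply(idx, function(i) paste(ann$assignments$gene[i], collapse = ";"), "")
    rg <- vapply(idx, function(i) paste(ann$assignments$region[i], collapse = ";"), "")
    pos <- match(adf$probe_id, names(idx))
    adf$gene_names <- ifelse(is.na(pos), "", gn[pos])
    adf$region_groups <- ifelse(is.na(pos), "", rg[pos])
  } else {
    adf$gene_names <- ""
    adf$region_groups <- ""
  }
  adf <- adf[, c("probe_id", "chr", "position", "gene_names", "region_groups",
                 "enhancer")]
  write_table(adf, fp("annotation.tsv"))
  write_table(cohort$metadata, fp("metadata.tsv"))
  write_table(cohort$truth$genes, fp("truth_genes.tsv"))
  write_table(cohort$truth$intergenic, fp("truth_intergenic.tsv"))
  invisible(directory)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param directory Directory holding the TSV file set.
#' @return A list with the same elements as a `synthetic_cohort` (truth tables
#'   included when present).
#' @export
read_cohort <- function(directory) {
  fp <- function(f) file.path(directory, f)
  for (f in c("expression.tsv", "methylation.tsv", "annotation.tsv", "metadata.tsv"))
    if (!file.exists(fp(f)))
      stop("missing input file '", fp(f), "'", call. = FALSE)
  meta <- read_metadata(fp("metadata.tsv"))
  out <- list(
    expression = read_matrix(fp("expression.tsv"), "log2_expression", meta),
    methylation = read_matrix(fp("methylation.tsv"), "beta", meta),
    annotation = read_annotation(fp("annotation.tsv")),
    metadata = meta)
  if (file.exists(fp("truth_genes.tsv")))
    out$truth <- list(
      genes = utils::read.delim(fp("truth_genes.tsv"), stringsAsFactors = FALSE,
                                na.strings = NULL),
      intergenic = utils::read.delim(fp("truth_intergenic.tsv"),
                                     stringsAsFactors = FALSE, na.strings = NULL))
  out
}
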