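#' Cross differential expression with differential methylation
#'
#' Takes the genes significant in both tables and classifies each by the
#' cross of its two directions: `hypo-up` (hypo-methylated, upregulated —
#' the candidate biomarker class), `hyper-down`, `hyper-up`, `hypo-down`.
#'
#' @param degs A `diff_table` from [call_degs()] (directions up/down).
#' @param dmgs A `diff_table` from [call_dmfs()] (directions hypo/hyper),
#'   typically from the ALL-region aggregate.
#' @param selector Label recorded for the methylation side (default the
#'   attribute-free `"ALL"`).
#' @return An object of class `overlap_classes`: data frame with `gene_id`,
#'   `deg_direction`, `dmg_direction`, `overlap_class`, `selector`; attributes
#'   `counts` (per-class table) and `hypo_up_fraction`.
#' @export
classify_overlap <- function(degs, dmgs, selector = "ALL") {
  sig_e <- degs[degs$significant, c("feature_id", "direction")]
  sig_m <- dmgs[dmgs$significant, c("feature_id", "direction")]
  common <- intersect(sig_e$feature_id, sig_m$feature_id)
  de <- sig_e$direction[match(common, sig_e$feature_id)]
  dm <- sig_m$direction[match(common, sig_m$feature_id)]
  out <- data.frame(gene_id = common,
                    deg_direction = de,
                    dmg_direction = dm,
                    overlap_class = paste(dm, de, sep = "-"),
                    selector = rep(selector, length(common)),
                    stringsAsFactors = FALSE)
  cls <- c("hypo-up", "hyper-down", "hyper-up", "hypo-down")
  counts <- stats::setNames(integer(4), cls)
  tb <- table(out$overlap_class)
  counts[names(tb)] <- as.integer(tb)
  attr(out, "counts") <- counts
  attr(out, "hypo_up_fraction") <-
    if (nrow(out) > 0) counts[["hypo-up"]] / nrow(out) else NA_real_
  class(out) <- c("overlap_classes", "data.frame")
  out
}

#' @export
print.overlap_classes <- function(x, ...) {
  cat(sprintf("overlap_classes: %d genes significant in both analyses\n", nrow(x)))
  cnt <- attr(x, "counts")
  cat(" ", paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "), "\n")
  if (nrow(x) > 0)
    cat(sprintf("  hypo-up fraction: %.3f\n", attr(x, "hypo_up_fraction")))
  invisible(x)
}

#' Dominant methylation-altered regions of one gene
#'
#' The dominant regions are the region with the smallest (most negative)
#' delta beta and every other present region whose delta lies strictly
#' within `tolerance` of that minimum.  Regions without probes for the gene
#' are never dominant.
#'
#' @param deltas Named numeric vector: region label -> delta beta for one
#'   gene (absent regions simply omitted; NA entries ignored).
#' @param tolerance Closeness bound (default 0.005, strict inequality).
#' @return Character vector of dominant region labels in canonical region
#'   order (independent of input order).
#' @export
dominant_regions <- function(deltas, tolerance = 0.005) {
  deltas <- deltas[!is.na(deltas)]
  if (length(deltas) == 0)
    stop("no region deltas available for the gene", call. = FALSE)
  if (is.null(names(deltas)) || !all(names(deltas) %in% REGION_LABELS))
    stop("deltas must be named by region label", call. = FALSE)
  mn <- min(deltas)
  dom <- names(deltas)[deltas - mn < tolerance]
  REGION_LABELS[REGION_LABELS %in% dom]
}

#' Dominant-region calls for a set of genes
#'
#' Computes per-region delta betas from per-selector region summaries and
#' applies the [dominant_regions()] rule to every requested gene.
#'
#' @param region_levels Named list of `region_level` objects, one per region
#'   selector (names are the region labels; an `ALL` entry is ignored).
#' @param genes Genes to call (default: union of genes present in any level).
#' @param tolerance Passed to [dominant_regions()].
#' @return Data frame with `gene_id`, one `delta_<region>` column per region,
#'   and `dominant` (semicolon-separated labels).
#' @export
dominant_region_table <- function(region_levels, genes = NULL, tolerance = 0.005) {
  region_levels <- region_levels[names(region_levels) %in% REGION_LABELS]
  if (length(region_levels) == 0)
    stop("no per-region levels supplied", call. = FALSE)
  deltas <- lapply(region_levels, delta_beta)
  if (is.null(genes))
    genes <- sort(unique(unlist(lapply(deltas, names), use.names = FALSE)))
  mat <- matrix(NA_real_, length(genes), length(region_levels),
                dimnames = list(genes, names(region_levels)))
  for (j in seq_along(deltas)) mat[, j] <- deltas[[j]][genes]
  dom <- vapply(seq_len(nrow(mat)), function(i) {
    d <- mat[i, ][!is.na(mat[i, ])]
    if (length(d) == 0) return(NA_character_)
    paste(dominant_regions(d, tolerance), collapse = ";")
  }, character(1))
  out <- data.frame(gene_id = genes, mat, dominant = unname(dom),
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out)[seq_along(region_levels) + 1] <- paste0("delta_", names(region_levels))
  rownames(out) <- NULL
  out
}

#' Correlate gene expression with region-level methylation
#'
#' Draws `n_per_group` case and control samples without replacement (fixed
#' seed), then computes the Pearson correlation between each gene's log2
#' expression and its mean beta value at each region, with the two-sided
#' t-based p-value.  Expression and methylation must share sample
#' identifiers (matched samples).
#'
#' @param expression A log2-scale [labeled_matrix()].
#' @param region_levels Named list of `region_level` objects per selector.
#' @param genes Genes to correlate.
#' @param n_per_group Samples drawn per group.
#' @param seed RNG seed for the draw.
#' @return Data frame `gene_id`, `region`, `r`, `p_value`; attributes
#'   `frac_negative` (fraction of negative correlations) and `n_sig_genes`
#'   (genes with any region p < 0.05).
#' @export
expr_meth_correlation <- function(expression, region_levels, genes,
                                  n_per_group, seed = 1) {
  stopifnot(inherits(expression, "labeled_matrix"))
  region_levels <- region_levels[names(region_levels) %in% REGION_LABELS]
  shared <- colnames(expression$values)
  for (lv in region_levels)
    shared <- intersect(shared, colnames(lv$beta_means))
  grp <- expression$group[match(shared, colnames(expression$values))]
  ncase <- sum(grp == "case"); nctrl <- sum(grp == "control")
  if (n_per_group > ncase || n_per_group > nctrl)
    stop("n_per_group (", n_per_group, ") exceeds available samples (case=",
         ncase, ", control=", nctrl, ")", call. = FALSE)
  set.seed(seed)
  take <- c(sample(shared[grp == "case"], n_per_group),
            sample(shared[grp == "control"], n_per_group))
  ex <- expression$values[, take, drop = FALSE]
  res <- list()
  for (rg in names(region_levels)) {
    bm <- region_levels[[rg]]$beta_means
    gs <- intersect(genes, rownames(bm))
    gs <- intersect(gs, rownames(ex))
    for (g in gs) {
      x <- ex[g, ]; y <- bm[g, take]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      res[[length(res) + 1]] <- data.frame(gene_id = g, region = rg,
                                           r = unname(ct$estimate),
                                           p_value = ct$p.value,
                                           stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res) > 0) do.call(rbind, res) else
    data.frame(gene_id = character(0), region = character(0),
               r = numeric(0), p_value = numeric(0))
  attr(out, "frac_negative") <- if (nrow(out) > 0) mean(out$r < 0) else NA_real_
  attr(out, "n_sig_genes") <-
    length(unique(out$gene_id[out$p_value < 0.05]))
  out
}
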