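#' Beta-value / M-value conversion
#'
#' The M-value is the logit2 transform of the methylation beta value,
#' `M = log2(beta / (1 - beta))`; it is the preferred scale for statistical
#' testing because its variance is approximately constant across the
#' methylation range, while the beta value retains the direct biological
#' interpretation as a methylated fraction.  Beta values are clamped to
#' `[eps, 1 - eps]` before the logit, since background-normalized arrays can
#' touch 0 or 1 exactly.
#'
#' @param beta Numeric vector/matrix of beta values in (0, 1).
#' @param m_value Numeric vector/matrix of M-values.
#' @param eps Clamping bound (default 1e-6).
#' @return `beta_to_m`: M-values; `m_to_beta`: beta values.  Shapes are
#'   preserved elementwise.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  if (any(!is.finite(beta)))
    stop("non-finite beta value", call. = FALSE)
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m_value) {
  if (any(!is.finite(m_value)))
    stop("non-finite M-value", call. = FALSE)
  # logistic in base 2, numerically stable at large |m|
  out <- stats::plogis(m_value * log(2))
  if (is.matrix(m_value)) dim(out) <- dim(m_value)
  out
}

#' Convert a beta-scale labeled matrix to M-values
#'
#' Convenience wrapper keeping the sample labels attached; the result is
#' suitable for [fit_group_model()].
#'
#' @param methylation A [labeled_matrix()] with scale `"beta"`.
#' @param eps Clamping bound passed to [beta_to_m()].
#' @return A `labeled_matrix` whose values are M-values (scale kept as
#'   `"log2_expression"`-like testing scale internally tagged `m_value`).
#' @export
as_m_values <- function(methylation, eps = 1e-6) {
  stopifnot(inherits(methylation, "labeled_matrix"))
  if (methylation$scale != "beta")
    stop("expected a beta-scale matrix", call. = FALSE)
  m <- methylation
  vals <- m$values
  na <- is.na(vals)
  vals[na] <- 0.5
  vals <- beta_to_m(vals, eps)
  vals[na] <- NA
  m$values <- vals
  m$scale <- "log2_expression"   # testing scale; group labels unchanged
  m
}

#' Region-level methylation summarization
#'
#' Measures the methylation level of each gene at a given region class as
#' the arithmetic mean beta value of the CpGs assigned to that gene with that
#' region label (selector `ALL` averages over the gene's CpGs in all six
#' region classes).  A probe assigned to several genes contributes to each of
#' them; genes with no qualifying probe are omitted.  Missing beta values are
#' excluded per sample.
#'
#' @param methylation A beta-scale [labeled_matrix()] of probes x samples.
#' @param annotation A [probe_annotation()].
#' @param selector One of `TSS1500, TSS200, 5UTR, 1stExon, Body, 3UTR, ALL`.
#' @return An object of class `region_level`: list with `selector`,
#'   `beta_means` (genes x samples matrix), `probe_counts`, `group`,
#'   `gender`.
#' @export
aggregate_region <- function(methylation, annotation, selector = "ALL") {
  stopifnot(inherits(methylation, "labeled_matrix"),
            inherits(annotation, "probe_annotation"))
  selector <- .normalize_region_or_all(selector)
  asg <- annotation$assignments
  if (selector != "ALL") asg <- asg[asg$region == selector, , drop = FALSE]
  # probe may map to several genes within the same region label: one
  # contribution per distinct (probe, gene) pair
  asg <- unique(asg[, c("probe_id", "gene")])
  asg <- asg[asg$probe_id %in% rownames(methylation$values), , drop = FALSE]
  if (nrow(asg) == 0) {
    warning("no probes match selector '", selector, "'")
    empty <- matrix(numeric(0), 0, ncol(methylation$values),
                    dimnames = list(NULL, colnames(methylation$values)))
    return(structure(list(selector = selector, beta_means = empty,
                          probe_counts = integer(0), group = methylation$group,
                          gender = methylation$gender),
                     class = "region_level"))
  }
  v <- methylation$values[asg$probe_id, , drop = FALSE]
  na <- is.na(v)
  v[na] <- 0
  sums <- rowsum(v, group = asg$gene)
  cnts <- rowsum((!na) * 1, group = asg$gene)
  means <- sums / cnts
  means[cnts == 0] <- NA
  pc <- as.integer(table(asg$gene)[rownames(sums)])
  structure(list(selector = selector, beta_means = means,
                 probe_counts = stats::setNames(pc, rownames(sums)),
                 group = methylation$group, gender = methylation$gender),
            class = "region_level")
}

.normalize_region_or_all <- function(selector) {
  if (identical(selector, "ALL")) return("ALL")
  .normalize_region(selector)
}

#' @export
print.region_level <- function(x, ...) {
  cat(sprintf("region_level[%s]: %d genes x %d samples\n",
              x$selector, nrow(x$beta_means), ncol(x$beta_means)))
  invisible(x)
}

#' Convert a region-level summary to a labeled matrix of M-values
#'
#' @param level A `region_level` from [aggregate_region()].
#' @return A [labeled_matrix()] of M-values of per-gene region means, ready
#'   for [fit_group_model()].
#' @export
region_m_values <- function(level) {
  stopifnot(inherits(level, "region_level"))
  as_m_values(labeled_matrix(level$beta_means, "beta", as.character(level$group),
                             level$gender))
}

#' Case-control delta of mean beta values
#'
#' `delta = mean beta(case) - mean beta(control)` per feature; negative
#' values mean hypo-methylation in cases.
#'
#' @param level A `region_level` or a beta-scale [labeled_matrix()]
#'   (probe-level).
#' @return Named numeric vector of deltas.
#' @export
delta_beta <- function(level) {
  if (inherits(level, "region_level")) {
    v <- level$beta_means; grp <- level$group
  } else if (inherits(level, "labeled_matrix")) {
    v <- level$values; grp <- level$group
  } else stop("expected a region_level or labeled_matrix", call. = FALSE)
  if (!all(c("case", "control") %in% grp))
    stop("both groups must be present", call. = FALSE)
  ca <- rowMeans(v[, grp == "case", drop = FALSE], na.rm = TRUE)
  co <- rowMeans(v[, grp == "control", drop = FALSE], na.rm = TRUE)
  ca - co
}

#' Decile thresholds of the delta-beta distribution
#'
#' The differential methylation caller keeps features whose delta beta lies
#' below the 0.1 quantile or above the 0.8 quantile of the all-feature delta
#' distribution.  Quantiles are computed by linear interpolation of order
#' statistics (the `h = (n - 1) q` convention, [stats::quantile()] type 7).
#'
#' @param deltas Numeric vector of deltas (>= 10 finite values required).
#' @param probs The two quantile levels (default `c(0.1, 0.8)`).
#' @return Named numeric `c(low = ..., high = ...)`.
#' @export
decile_thresholds <- function(deltas, probs = c(0.1, 0.8)) {
  d <- deltas[is.finite(deltas)]
  if (length(d) < 10)
    stop("need at least 10 finite delta values", call. = FALSE)
  q <- stats::quantile(d, probs = probs, type = 7, names = FALSE)
  c(low = q[1], high = q[2])
}

#' Call differentially methylated features
#'
#' The dual criterion: a gene (or intergenic CpG) is significantly
#' differentially methylated iff its delta beta falls below the low decile
#' threshold or above the high one (strict), AND its BH-adjusted M-value
#' p-value is below `alpha`.  BH adjustment is applied across the supplied
#' feature list.
#'
#' @param m_stats [fit_group_model()] output on M-values for the same
#'   features.
#' @param deltas Named delta-beta vector (names = feature IDs).
#' @param thresholds Output of [decile_thresholds()] (or any `c(low, high)`).
#' @param alpha BH-adjusted p cutoff (default 0.05).
#' @return A `diff_table` with `effect` = delta beta and direction
#'   `hypo`/`hyper`/`none`.
#' @export
call_dmfs <- function(m_stats, deltas, thresholds, alpha = 0.05) {
  if (!setequal(m_stats$feature_id, names(deltas)))
    stop("feature lists of m_stats and deltas disagree", call. = FALSE)
  deltas <- deltas[m_stats$feature_id]
  out <- data.frame(feature_id = m_stats$feature_id,
                    effect = unname(deltas),
                    t_stat = m_stats$t_stat,
                    p_value = m_stats$p_value,
                    stringsAsFactors = FALSE)
  out$adj_p <- bh_adjust(out$p_value)
  lo <- thresholds[["low"]]; hi <- thresholds[["high"]]
  extreme <- out$effect < lo | out$effect > hi
  out$significant <- !is.na(out$adj_p) & extreme & out$adj_p < alpha
  out$direction <- ifelse(!out$significant, "none",
                          ifelse(out$effect < lo, "hypo", "hyper"))
  class(out) <- c("diff_table", "data.frame")
  out
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Without continuity correction by default (a flag restores the Yates
#' correction), df = 1.  P-values that underflow double precision are
#' reported as the smallest positive normal double, preserving comparisons
#' against printed bounds such as 2.2e-16.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return List with `table`, `statistic`, `p_value`.
#' @export
chisq_2x2 <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0))
    stop("expected a 2x2 table of non-negative counts", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: zero marginal", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  p <- max(unname(ct$p.value), .Machine$double.xmin)
  list(table = tab, statistic = unname(ct$statistic), p_value = p)
}

#' Enhancer enrichment among differential intergenic CpGs
#'
#' Builds the 2x2 table (rows: differential / non-differential CpG; columns:
#' enhancer-associated / non-enhancer) from the intergenic differential calls
#' and the probe annotation, and tests independence with the Pearson
#' chi-square ([chisq_2x2()]).
#'
#' @param dmc_calls A `diff_table` over intergenic probes ([call_dmfs()]).
#' @param annotation A [probe_annotation()]; every feature of `dmc_calls`
#'   must be an intergenic probe in it.
#' @param correct Yates correction flag, passed through.
#' @return List with `table` (2x2, dimnames set), `statistic`, `p_value`.
#' @export
enhancer_enrichment <- function(dmc_calls, annotation, correct = FALSE) {
  stopifnot(inherits(annotation, "probe_annotation"))
  pr <- annotation$probes
  idx <- match(dmc_calls$feature_id, pr$probe_id)
  if (anyNA(idx))
    stop("feature(s) absent from annotation: ",
         paste(utils::head(dmc_calls$feature_id[is.na(idx)], 3), collapse = ", "),
         call. = FALSE)
  if (!all(pr$intergenic[idx]))
    stop("all features must be intergenic probes", call. = FALSE)
  enh <- pr$enhancer[idx]
  diffg <- dmc_calls$significant
  tab <- matrix(c(sum(diffg & enh), sum(diffg & !enh),
                  sum(!diffg & enh), sum(!diffg & !enh)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("differential", "non-differential"),
                                c("enhancer", "non-enhancer")))
  chisq_2x2(tab, correct = correct)
}
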