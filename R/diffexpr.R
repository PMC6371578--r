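#' Two-group linear model fit per feature
#'
#' Fits the case-vs-control linear model to every feature of a
#' [labeled_matrix()] and returns the effect (difference of group means:
#' case minus control), the t statistic and its two-sided p-value.
#'
#' With `moderated = TRUE` (the default) the per-feature variances are shrunk
#' toward a common prior by empirical Bayes, i.e. the moderated t of
#' limma, with posterior variance `(d0*s0^2 + d*s^2) / (d0 + d)` on
#' `d0 + d` degrees of freedom.  With `moderated = FALSE` the ordinary
#' pooled-variance two-sample t on `n - 2` degrees of freedom is computed;
#' this path exists mainly as an exact, hand-checkable reference.
#'
#' Zero-variance features: under moderation the prior variance takes over; in
#' the ordinary fit a feature whose two group means are also equal gets
#' `t = 0, p = 1`.
#'
#' @param matrix A [labeled_matrix()] on the log2 expression scale, or a plain
#'   feature-by-sample numeric matrix of M-values with a `group` argument
#'   supplied via an attached `labeled_matrix`.
#' @param moderated Logical; empirical-Bayes moderation (default `TRUE`).
#' @return Data frame with columns `feature_id`, `effect`, `t_stat`,
#'   `p_value`.
#' @export
fit_group_model <- function(matrix, moderated = TRUE) {
  if (!inherits(matrix, "labeled_matrix"))
    stop("'matrix' must be a labeled_matrix", call. = FALSE)
  v <- matrix$values
  grp <- matrix$group
  n1 <- sum(grp == "case"); n2 <- sum(grp == "control")
  if (n1 < 2 || n2 < 2)
    stop("each group needs at least 2 samples (case=", n1, ", control=", n2, ")",
         call. = FALSE)
  case <- v[, grp == "case", drop = FALSE]
  ctrl <- v[, grp == "control", drop = FALSE]
  effect <- rowMeans(case) - rowMeans(ctrl)

  if (moderated) {
    design <- cbind(Intercept = 1, case = as.numeric(grp == "case"))
    res <- tryCatch({
      fit <- limma::eBayes(limma::lmFit(v, design))
      list(t = fit$t[, "case"], p = fit$p.value[, "case"])
    }, error = function(e) NULL)
    if (is.null(res)) {
      # variance estimation degenerated: pool all residual variances
      s2 <- (rowSums((case - rowMeans(case))^2) +
               rowSums((ctrl - rowMeans(ctrl))^2)) / (n1 + n2 - 2)
      s2p <- rep(mean(s2), length(effect))
      tt <- effect / sqrt(s2p * (1 / n1 + 1 / n2))
      res <- list(t = tt, p = 2 * stats::pt(-abs(tt), df = n1 + n2 - 2))
    }
    tt <- res$t; pp <- res$p
  } else {
    s2 <- (rowSums((case - rowMeans(case))^2) +
             rowSums((ctrl - rowMeans(ctrl))^2)) / (n1 + n2 - 2)
    se <- sqrt(s2 * (1 / n1 + 1 / n2))
    tt <- effect / se
    zero <- se == 0 & effect == 0
    tt[zero] <- 0
    pp <- 2 * stats::pt(-abs(tt), df = n1 + n2 - 2)
  }
  data.frame(feature_id = rownames(v), effect = unname(effect),
             t_stat = unname(tt), p_value = unname(pp),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts p-values by the BH step-up rule across all features:
#' `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1, returned in input
#' order.  `NA` entries are excluded from the adjustment (the effective `m`
#' is the number of non-missing values) and returned as `NA`.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(p_values))
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  out
}

#' Call differentially expressed genes
#'
#' Applies BH adjustment across all features jointly, then the dual
#' threshold: significant iff `adj_p < alpha` and `|log2FC| > min_abs_lfc`
#' (both inequalities strict).  Direction is the sign of the effect.
#'
#' @param stats Output of [fit_group_model()] over all features.
#' @param alpha BH-adjusted p-value cutoff (default 0.05).
#' @param min_abs_lfc Minimum absolute log2 fold change (default 0.1).
#' @return A `diff_table` data frame: `feature_id`, `effect`, `t_stat`,
#'   `p_value`, `adj_p`, `significant`, `direction` (`up`/`down`/`none`).
#' @export
call_degs <- function(stats, alpha = 0.05, min_abs_lfc = 0.1) {
  out <- stats
  out$adj_p <- bh_adjust(out$p_value)
  out$significant <- !is.na(out$adj_p) & out$adj_p < alpha &
    abs(out$effect) > min_abs_lfc
  out$direction <- ifelse(!out$significant, "none",
                          ifelse(out$effect > 0, "up", "down"))
  class(out) <- c("diff_table", "data.frame")
  out
}

#' @export
print.diff_table <- function(x, ...) {
  cat(sprintf("diff_table: %d features, %d significant (%s)\n",
              nrow(x), sum(x$significant),
              paste(sprintf("%s=%d", names(table(x$direction[x$significant])),
                            table(x$direction[x$significant])), collapse = ", ")))
  invisible(x)
}
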