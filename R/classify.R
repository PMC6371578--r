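#' Assemble a samples-by-features table for classification
#'
#' Builds the classifier input from either gene expression (log2 scale) or a
#' region-level methylation summary, restricted to a feature panel, with an
#' optional gender column encoded as a 0/1 feature (`female = 0, male = 1`;
#' `unknown` is rejected).
#'
#' @param data A [labeled_matrix()] (expression) or `region_level`
#'   (methylation).
#' @param features Feature identifiers to keep (default all).
#' @param source Label recorded on the table: `"expression_log2"`,
#'   `"beta_all_regions"` or `"beta_dominant_regions"`.
#' @param include_gender Add the gender feature (default `FALSE`).
#' @return An object of class `feature_table`: list with `x` (samples x
#'   features matrix), `labels` (factor case/control), `source`.
#' @export
feature_table <- function(data, features = NULL,
                          source = c("expression_log2", "beta_all_regions",
                                     "beta_dominant_regions"),
                          include_gender = FALSE) {
  source <- match.arg(source)
  if (inherits(data, "labeled_matrix")) {
    v <- data$values; grp <- data$group; gender <- data$gender
  } else if (inherits(data, "region_level")) {
    v <- data$beta_means; grp <- data$group; gender <- data$gender
  } else stop("expected a labeled_matrix or region_level", call. = FALSE)
  if (is.null(features)) features <- rownames(v)
  miss <- setdiff(features, rownames(v))
  if (length(miss) > 0)
    stop("feature(s) absent from table: ", paste(utils::head(miss, 5), collapse = ", "),
         call. = FALSE)
  x <- t(v[features, , drop = FALSE])
  if (include_gender) {
    if (is.null(gender) || any(gender == "unknown"))
      stop("gender feature requested but gender labels are missing/unknown",
           call. = FALSE)
    x <- cbind(x, gender = as.numeric(gender == "male"))
  }
  if (anyNA(x))
    stop("feature table contains missing values; impute or drop upstream",
         call. = FALSE)
  if (length(unique(grp)) < 2)
    stop("both classes must be present", call. = FALSE)
  structure(list(x = x, labels = factor(as.character(grp),
                                        levels = c("case", "control")),
                 source = source),
            class = "feature_table")
}

# reproducible fold/panel seed stream derived from the master seed
.fold_seed <- function(seed, fold, k = 0L) {
  as.integer((as.numeric(seed) * 48271 + fold * 9973 + k * 101) %% 2147483629) + 1L
}

#' Importance ranking by per-fold random forests
#'
#' For each leave-one-out fold, fits a random forest on the n-1 training
#' samples and records the impurity-decrease (mean decrease in Gini)
#' importance of every feature; reports the per-feature mean across folds
#' and the descending ranking, ties broken by feature identifier.
#'
#' @param table A [feature_table()].
#' @param n_trees Trees per forest (default 500).
#' @param mtry Candidate features per split (default `sqrt(p)`).
#' @param seed Master seed; each fold's RNG derives from it.
#' @return Data frame `feature`, `importance`, sorted by decreasing mean
#'   importance.
#' @export
rank_importance <- function(table, n_trees = 500, mtry = NULL, seed = 1) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$x; y <- table$labels
  n <- nrow(x)
  if (min(table(y)) < 2)
    stop("each class needs at least 2 samples", call. = FALSE)
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(ncol(x))))
  imp <- matrix(0, n, ncol(x), dimnames = list(NULL, colnames(x)))
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2)
      stop("training fold ", i, " contains a single class", call. = FALSE)
    set.seed(.fold_seed(seed, i))
    rf <- randomForest::randomForest(x[-i, , drop = FALSE], ytr,
                                     ntree = n_trees, mtry = mtry)
    imp[i, ] <- rf$importance[, "MeanDecreaseGini"]
  }
  mean_imp <- colMeans(imp)
  ord <- order(-mean_imp, names(mean_imp))
  data.frame(feature = names(mean_imp)[ord],
             importance = unname(mean_imp)[ord],
             stringsAsFactors = FALSE)
}

#' Leave-one-out cross-validated case probabilities
#'
#' For each sample, trains a random forest on all other samples and scores
#' the held-out sample; the score is the fraction of trees voting `case`.
#' Each fold's RNG is derived from `(seed, fold index, |features|)`, so
#' results are reproducible and invariant to fold order.
#'
#' @param table A [feature_table()].
#' @param features Feature subset to use (must exist in the table).
#' @param n_trees,mtry,seed As in [rank_importance()].
#' @return Named numeric vector of out-of-fold case probabilities in
#'   \[0, 1\], one per sample.
#' @export
loocv_scores <- function(table, features, n_trees = 500, mtry = NULL, seed = 1) {
  stopifnot(inherits(table, "feature_table"))
  miss <- setdiff(features, colnames(table$x))
  if (length(miss) > 0)
    stop("feature(s) not in table: ", paste(miss, collapse = ", "), call. = FALSE)
  x <- table$x[, features, drop = FALSE]
  y <- table$labels
  n <- nrow(x)
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(ncol(x))))
  scores <- numeric(n)
  k <- length(features)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2)
      stop("training fold ", i, " contains a single class", call. = FALSE)
    set.seed(.fold_seed(seed, i, k))
    rf <- randomForest::randomForest(x[-i, , drop = FALSE], ytr,
                                     ntree = n_trees, mtry = mtry)
    scores[i] <- stats::predict(rf, x[i, , drop = FALSE],
                                type = "prob")[, "case"]
  }
  stats::setNames(scores, rownames(x))
}

#' ROC curve, AUC and rank-sum p-value
#'
#' AUC via the Mann-Whitney identity (concordant case/control score pairs,
#' ties counted 1/2); the p-value is the two-sided normal-approximation
#' Wilcoxon rank-sum test with tie correction comparing case and control
#' scores; ROC points from the sweep over all unique score thresholds.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Factor or character, values `case`/`control`.
#' @return List with `roc` (data frame `threshold`, `fpr`, `tpr`), `auc`,
#'   `p_value`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.character(labels)
  case <- scores[labels == "case"]; ctrl <- scores[labels == "control"]
  n1 <- length(case); n0 <- length(ctrl)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present", call. = FALSE)
  r <- rank(c(case, ctrl))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  p <- if (stats::sd(scores) == 0) 1 else
    suppressWarnings(stats::wilcox.test(case, ctrl, exact = FALSE,
                                        correct = FALSE)$p.value)
  thr <- sort(unique(scores), decreasing = TRUE)
  roc <- data.frame(threshold = c(Inf, thr),
                    fpr = c(0, vapply(thr, function(t) mean(ctrl >= t), 0)),
                    tpr = c(0, vapply(thr, function(t) mean(case >= t), 0)))
  list(roc = roc, auc = auc, p_value = p)
}

#' Incremental importance-ranked panel selection
#'
#' Adds the importance-ranked features to the classifier one by one; for
#' each panel size k the LOOCV AUC is recorded, and the best panel is the
#' smallest k maximizing AUC.  The returned result carries the best panel's
#' ROC curve, AUC and rank-sum p-value.
#'
#' @param table A [feature_table()].
#' @param ranked_features Character vector in importance order (e.g. the
#'   `feature` column of [rank_importance()]).
#' @param n_trees,mtry,seed As in [loocv_scores()].
#' @param max_k Largest panel size to evaluate (default all ranked features).
#' @return An object of class `panel_result`: list with `ranked_features`,
#'   `auc_by_k` (named numeric), `best_k`, `best_panel`, `scores` (best
#'   panel's out-of-fold scores), `roc_points`, `auc`, `p_value`, `seed`.
#' @export
incremental_panel <- function(table, ranked_features, n_trees = 500,
                              mtry = NULL, seed = 1,
                              max_k = length(ranked_features)) {
  if (length(ranked_features) == 0)
    stop("ranked_features must be nonempty", call. = FALSE)
  K <- min(max_k, length(ranked_features))
  auc_by_k <- stats::setNames(numeric(K), as.character(seq_len(K)))
  all_scores <- vector("list", K)
  for (k in seq_len(K)) {
    sc <- loocv_scores(table, ranked_features[seq_len(k)],
                       n_trees = n_trees, mtry = mtry, seed = seed)
    all_scores[[k]] <- sc
    auc_by_k[k] <- roc_auc(sc, table$labels)$auc
  }
  best_k <- unname(which.max(auc_by_k))  # smallest k on ties
  best <- roc_auc(all_scores[[best_k]], table$labels)
  structure(list(ranked_features = ranked_features,
                 auc_by_k = auc_by_k,
                 best_k = best_k,
                 best_panel = ranked_features[seq_len(best_k)],
                 scores = all_scores[[best_k]],
                 roc_points = best$roc,
                 auc = best$auc,
                 p_value = best$p_value,
                 seed = seed),
            class = "panel_result")
}

#' @export
print.panel_result <- function(x, ...) {
  cat(sprintf("panel_result: best k = %d of %d ranked features\n",
              x$best_k, length(x$ranked_features)))
  cat(sprintf("  LOOCV AUC = %.3f, rank-sum p = %.3g\n", x$auc, x$p_value))
  invisible(x)
}

#' Cross-cohort validation of a fixed panel
#'
#' Fits one random forest with the panel features on the full training
#' cohort, scores every sample of an independent cohort, and reports the AUC
#' and rank-sum p-value against that cohort's labels.  Used to check disease
#' specificity: a cohort whose signal genes are disjoint from the panel
#' should score near AUC 0.5.
#'
#' @param table Training [feature_table()].
#' @param panel Character vector of panel features (must be present in both
#'   tables).
#' @param other_table Validation [feature_table()].
#' @param n_trees,mtry,seed As elsewhere.
#' @return List with `auc`, `p_value`, `roc`, `scores`.
#' @export
cross_cohort_validate <- function(table, panel, other_table, n_trees = 500,
                                  mtry = NULL, seed = 1) {
  for (tb in list(table, other_table)) {
    miss <- setdiff(panel, colnames(tb$x))
    if (length(miss) > 0)
      stop("panel feature(s) missing from cohort: ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(length(panel))))
  set.seed(.fold_seed(seed, 0L, length(panel)))
  rf <- randomForest::randomForest(table$x[, panel, drop = FALSE],
                                   table$labels, ntree = n_trees, mtry = mtry)
  sc <- stats::predict(rf, other_table$x[, panel, drop = FALSE],
                       type = "prob")[, "case"]
  res <- roc_auc(sc, other_table$labels)
  list(auc = res$auc, p_value = res$p_value, roc = res$roc, scores = sc)
}
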