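# small planted classification problem: one strong separator + noise
toy_table <- function(n = 30, p_noise = 10, sep_shift = 3, seed = 11) {
  set.seed(seed)
  grp <- rep(c("case", "control"), each = n / 2)
  x <- matrix(rnorm(n * (p_noise + 1)), n,
              dimnames = list(sprintf("s%02d", 1:n),
                              c("sep", sprintf("noise%02d", 1:p_noise))))
  x[grp == "case", "sep"] <- x[grp == "case", "sep"] + sep_shift
  v <- t(x)
  structure(list(x = x, labels = factor(grp, c("case", "control")),
                 source = "expression_log2"), class = "feature_table")
}

test_that("feature_table assembles panels and the gender feature", {
  co <- small_cohort()
  genes <- hypo_up_truth(co)
  ft <- feature_table(co$expression, genes, "expression_log2",
                      include_gender = TRUE)
  expect_equal(colnames(ft$x), c(genes, "gender"))
  expect_setequal(unique(ft$x[, "gender"]), c(0, 1))
  expect_equal(nrow(ft$x), ncol(co$expression$values))
  expect_error(feature_table(co$expression, c(genes, "NOPE")), "NOPE")
})

test_that("importance ranking puts a perfect separator first", {
  tab <- toy_table(n = 60, p_noise = 20, sep_shift = 4, seed = 21)
  rk <- rank_importance(tab, n_trees = 150, seed = 21)
  expect_equal(rk$feature[1], "sep")
  expect_equal(nrow(rk), 21)             # every feature reported once
  expect_true(all(is.finite(rk$importance)))
  # duplicated feature columns both get finite importance
  tab2 <- tab; tab2$x <- cbind(tab$x, sep2 = tab$x[, "sep"])
  rk2 <- rank_importance(tab2, n_trees = 100, seed = 21)
  expect_equal(nrow(rk2), 22)
  # deterministic per seed
  rk3 <- rank_importance(tab, n_trees = 150, seed = 21)
  expect_identical(rk, rk3)
})

test_that("LOOCV scores separate a separable toy and are reproducible", {
  v <- matrix(c(0.9, 0.8, 0.1, 0.2), 1, 4,
              dimnames = list("f1", paste0("s", 1:4)))
  tab <- structure(list(x = t(v), labels = factor(c("case", "case",
                                                    "control", "control"),
                                                  c("case", "control")),
                        source = "expression_log2"), class = "feature_table")
  sc <- loocv_scores(tab, "f1", n_trees = 100, seed = 2)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_equal(roc_auc(sc, tab$labels)$auc, 1)
  expect_identical(sc, loocv_scores(tab, "f1", n_trees = 100, seed = 2))
  expect_error(loocv_scores(tab, "f2", n_trees = 50, seed = 1), "f2")
  # sample order does not change a sample's score
  perm <- c(3, 1, 4, 2)
  tabp <- structure(list(x = tab$x[perm, , drop = FALSE],
                         labels = tab$labels[perm],
                         source = tab$source), class = "feature_table")
  scp <- loocv_scores(tabp, "f1", n_trees = 100, seed = 2)
  expect_identical(sc[names(scp)], scp)
})

test_that("AUC follows the Mann-Whitney identity and pair-counting oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2),
                       c("case", "case", "control", "control"))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), rep(c("case", "control"), 3))$auc, 0.5)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.1),
                       c("case", "case", "control", "control"))$auc, 0.75)
  expect_error(roc_auc(1:3, rep("case", 3)), "both classes")
  set.seed(19)
  for (rep in 1:40) {
    n1 <- sample(2:12, 1); n0 <- sample(2:12, 1)
    sc <- round(runif(n1 + n0), 2)       # rounding forces ties
    lab <- c(rep("case", n1), rep("control", n0))
    expect_equal(roc_auc(sc, lab)$auc,
                 auc_oracle(sc[1:n1], sc[n1 + 1:n0]), tolerance = 1e-12)
  }
  # ROC endpoints span (0,0) to (1,1)
  r <- roc_auc(runif(20), rep(c("case", "control"), 10))$roc
  expect_equal(unlist(r[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r[nrow(r), c("fpr", "tpr")]), c(fpr = 1, tpr = 1))
})

test_that("incremental panel tracks AUC by k and picks the smallest best k", {
  tab <- toy_table(n = 30, p_noise = 4, sep_shift = 4, seed = 5)
  rk <- rank_importance(tab, n_trees = 100, seed = 5)
  pan <- incremental_panel(tab, rk$feature, n_trees = 100, seed = 5, max_k = 3)
  expect_equal(length(pan$auc_by_k), 3)
  expect_equal(pan$best_k, unname(which.max(pan$auc_by_k)))
  expect_equal(pan$best_panel, rk$feature[seq_len(pan$best_k)])
  expect_equal(pan$auc, max(pan$auc_by_k))
  # K = 1 bookkeeping
  pan1 <- incremental_panel(tab, rk$feature[1], n_trees = 100, seed = 5)
  expect_equal(length(pan1$auc_by_k), 1)
  expect_equal(pan1$best_k, 1L)
  expect_error(incremental_panel(tab, character(0)), "nonempty")
})

test_that("cross-cohort validation transfers matched signal, rejects missing genes", {
  base <- list(n_case = 30, n_control = 30, n_genes = 200, probes_per_region = 0,
               n_intergenic = 0, n_hypo_up = 15, n_diff_intergenic = 0,
               expr_effect = 1)
  a <- generate_cohort(do.call(sim_config, c(base, seed = 61, plant_seed = 8)))
  b <- generate_cohort(do.call(sim_config, c(base, seed = 62, plant_seed = 8)))
  genes <- hypo_up_truth(a)
  fa <- feature_table(a$expression, genes, "expression_log2")
  fb <- feature_table(b$expression, genes, "expression_log2")
  cv <- cross_cohort_validate(fa, genes, fb, n_trees = 200, seed = 61)
  expect_gte(cv$auc, 0.85)
  expect_error(cross_cohort_validate(fa, c(genes, "MISSING"), fb),
               "MISSING")
})

test_that("gender feature does not hurt a gender-informative cohort", {
  cfg <- function(s) sim_config(n_case = 30, n_control = 30, n_genes = 150,
                                probes_per_region = 0, n_intergenic = 0,
                                n_hypo_up = 10, n_diff_intergenic = 0,
                                expr_effect = 0.8, gender_effect = 0.5, seed = s)
  co <- generate_cohort(cfg(71))
  genes <- hypo_up_truth(co)
  plain <- feature_table(co$expression, genes, "expression_log2")
  withg <- feature_table(co$expression, genes, "expression_log2",
                         include_gender = TRUE)
  auc0 <- roc_auc(loocv_scores(plain, genes, n_trees = 150, seed = 71),
                  plain$labels)$auc
  auc1 <- roc_auc(loocv_scores(withg, c(genes, "gender"), n_trees = 150,
                               seed = 71), withg$labels)$auc
  expect_gt(auc1, auc0 - 0.1)
})
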