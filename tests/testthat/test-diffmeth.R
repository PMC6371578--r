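test_that("beta/M transforms match their closed forms and invert exactly", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(m_to_beta(0), 0.5)
  grid <- seq(0.001, 0.999, by = 0.001)
  expect_lt(max(abs(grid - m_to_beta(beta_to_m(grid)))), 1e-12)
  # strictly increasing
  expect_true(all(diff(beta_to_m(grid)) > 0))
  expect_error(beta_to_m(c(0.2, NA)), "non-finite")
  expect_error(m_to_beta(Inf), "non-finite")
  # clamping keeps the logit finite at the boundaries
  expect_true(all(is.finite(beta_to_m(c(0, 1)))))
})

test_that("region aggregation averages the right probes per gene", {
  ann <- read_annotation(write_fixture_annotation(c(
    "cg1\t1\t100\tG\tTSS200\t",
    "cg2\t1\t200\tG\tTSS200\t",
    "cg3\t1\t300\tG\tTSS1500\t",
    "cg4\t1\t400\tG;H\tBody;Body\t",
    "cg5\t1\t500\tG\tBody\t",
    "cg6\t1\t900\t\t\tTRUE")))
  b <- matrix(c(0.2, 0.4, 0.1, 0.3, 0.5, 0.9), 6, 4,
              dimnames = list(paste0("cg", 1:6), paste0("s", 1:4)))
  lm <- labeled_matrix(b, "beta", c("case", "case", "control", "control"))
  ts200 <- aggregate_region(lm, ann, "TSS200")
  expect_equal(unname(ts200$beta_means["G", "s1"]), 0.3)   # mean(0.2, 0.4)
  # multi-gene probe contributes to both genes
  body <- aggregate_region(lm, ann, "Body")
  expect_equal(unname(body$beta_means["H", "s1"]), 0.3)
  expect_equal(unname(body$beta_means["G", "s1"]), 0.4)    # mean(0.3, 0.5)
  # ALL pools every gene-region CpG; intergenic cg6 contributes nowhere
  all_lv <- aggregate_region(lm, ann, "ALL")
  expect_equal(unname(all_lv$beta_means["G", "s1"]), 0.3)  # mean of cg1..cg5
  expect_equal(unname(all_lv$probe_counts["G"]), 5L)
  expect_false("cg6" %in% rownames(all_lv$beta_means))
  # permutation of probe order leaves the aggregate unchanged
  perm <- sample(6)
  lm2 <- labeled_matrix(b[perm, ], "beta", c("case", "case", "control", "control"))
  expect_equal(aggregate_region(lm2, ann, "ALL")$beta_means, all_lv$beta_means)
  # empty selector result warns and returns an empty level
  expect_warning(lv0 <- aggregate_region(lm, ann, "5UTR"), "no probes")
  expect_equal(nrow(lv0$beta_means), 0)
})

test_that("delta beta is the case-minus-control mean difference", {
  b <- matrix(c(0.30, 0.30, 0.35, 0.35,
                0.5, 0.5, 0.5, 0.5), 2, 4, byrow = TRUE,
              dimnames = list(c("p1", "p2"), paste0("s", 1:4)))
  lm <- labeled_matrix(b, "beta", c("case", "case", "control", "control"))
  d <- delta_beta(lm)
  expect_equal(unname(d["p1"]), -0.05)
  expect_equal(unname(d["p2"]), 0)
})

test_that("decile thresholds use (n-1)q interpolation and match the oracle", {
  thr <- decile_thresholds(c(-10, -8, -6, -4, -2, 0, 2, 4, 6, 8))
  expect_equal(unname(thr), c(-8.2, 4.4))
  expect_equal(unname(decile_thresholds(rep(3, 12))), c(3, 3))
  expect_error(decile_thresholds(1:5), "at least 10")
  set.seed(13)
  for (rep in 1:20) {
    x <- rnorm(sample(10:200, 1))
    thr <- decile_thresholds(x)
    expect_lt(abs(thr[["low"]] - quantile_oracle(x, 0.1)), 1e-12)
    expect_lt(abs(thr[["high"]] - quantile_oracle(x, 0.8)), 1e-12)
  }
})

test_that("differential methylation requires both decile and FDR criteria", {
  ms <- data.frame(feature_id = c("a", "b", "c", "d"),
                   effect = 0, t_stat = c(-9, -9, 9, 0),
                   p_value = c(1e-8, 1e-8, 1e-8, 0.2))
  deltas <- c(a = -0.06, b = -0.05, c = 0.07, d = 0.001)
  thr <- c(low = -0.05, high = 0.05)
  tab <- call_dmfs(ms, deltas, thr)
  expect_true(tab$significant[1])
  expect_false(tab$significant[2])          # delta == low: strict <
  expect_identical(tab$direction, c("hypo", "none", "hyper", "none"))
  # significant requires the adjusted p too
  ms2 <- ms; ms2$p_value <- c(0.5, 0.5, 0.5, 0.5)
  expect_false(any(call_dmfs(ms2, deltas, thr)$significant))
  expect_error(call_dmfs(ms, deltas[1:3], thr), "disagree")
  # hypo+hyper calls bounded by the decile mass
  set.seed(5)
  n <- 500
  msr <- data.frame(feature_id = paste0("f", 1:n), effect = 0,
                    t_stat = rnorm(n), p_value = runif(n))
  dr <- setNames(rnorm(n), msr$feature_id)
  tabr <- call_dmfs(msr, dr, decile_thresholds(dr))
  expect_lte(sum(tabr$significant), ceiling(0.3 * n) + 2)
})

test_that("2x2 chi-square matches the closed form and handles Table-2 scale", {
  r <- chisq_2x2(matrix(c(20, 10, 10, 20), 2, 2, byrow = TRUE))
  expect_equal(r$statistic, chisq_oracle(20, 10, 10, 20), tolerance = 1e-12)
  expect_equal(r$statistic, 6.667, tolerance = 1e-3)
  expect_equal(r$p_value, 0.00982, tolerance = 1e-3)
  r0 <- chisq_2x2(matrix(10, 2, 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_error(chisq_2x2(matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)),
               "degenerate")
  set.seed(8)
  for (rep in 1:50) {
    tb <- matrix(rpois(4, 40) + 1, 2, 2)
    expect_lt(abs(chisq_2x2(tb)$statistic -
                    chisq_oracle(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2])), 1e-9)
  }
})

test_that("enhancer enrichment builds the table from calls and annotation", {
  ann <- read_annotation(write_fixture_annotation(c(
    "cg1\t1\t1\t\t\tTRUE", "cg2\t1\t2\t\t\tTRUE",
    "cg3\t1\t3\t\t\t", "cg4\t1\t4\t\t\t",
    "cg5\t1\t5\t\t\tTRUE", "cg6\t1\t6\t\t\t",
    "cg7\t1\t7\tG\tBody\t")))
  calls <- data.frame(feature_id = paste0("cg", 1:6),
                      significant = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  r <- enhancer_enrichment(calls, ann)
  expect_equal(unname(r$table["differential", ]), c(2, 1))
  expect_equal(unname(r$table["non-differential", ]), c(1, 2))
  # gene-bound probe is rejected
  expect_error(enhancer_enrichment(
    data.frame(feature_id = "cg7", significant = TRUE), ann), "intergenic")
})
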