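test_that("matrix round-trips through TSV with metadata intact", {
  m <- matrix(c(1.5, 2.25, 3, 0.1, 0.2, 0.3, 4, 5, 6, 7, 8, 9), nrow = 3,
              dimnames = list(c("G1", "G2", "G3"), c("s1", "s2", "s3", "s4")))
  meta <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                     group = c("case", "case", "control", "control"),
                     gender = c("male", "female", "male", "female"))
  f <- tempfile(); fm <- tempfile()
  utils::write.table(data.frame(ID = rownames(m), m), f, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(meta, fm, sep = "\t", quote = FALSE, row.names = FALSE)
  lm <- read_matrix(f, "log2_expression", fm)
  expect_equal(dim(lm), c(3L, 4L))
  expect_equal(as.character(lm$group), meta$group)
  expect_equal(lm$values, m)
})

test_that("invalid matrices are rejected with context", {
  meta <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                     group = c("case", "case", "control", "control"))
  m <- matrix(runif(8), 2, 4, dimnames = list(c("A", "B"), meta$sample_id))
  f <- tempfile()
  # beta value far out of range names the offending cell
  m2 <- m; m2["B", "s3"] <- 1.2
  expect_error(labeled_matrix(m2, "beta", meta$group), "B.*s3")
  # tiny overshoot is clamped
  m3 <- m; m3[1, 1] <- 1 + 1e-10
  expect_equal(labeled_matrix(m3, "beta", meta$group)$values[1, 1], 1)
  # duplicated feature IDs
  utils::write.table(data.frame(ID = c("A", "A"), m), f, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_matrix(f, "log2_expression", meta), "duplicated feature ID")
  # sample without a group label
  expect_error(labeled_matrix(m, "beta", c("case", "case", "control", "x")),
               "case.*control")
})

test_that("annotation parsing expands and deduplicates gene-region pairs", {
  p <- write_fixture_annotation(c(
    "cg0001\t1\t1000\tGENEA;GENEA\tTSS200;Body\tTRUE",
    "cg0002\t2\t500\t\t\t",
    "cg0003\t3\t700\tGENEB;GENEB\tTSS200;TSS200\tFALSE"))
  ann <- read_annotation(p)
  expect_equal(nrow(ann$probes), 3)
  a1 <- ann$assignments[ann$assignments$probe_id == "cg0001", ]
  expect_setequal(paste(a1$gene, a1$region), c("GENEA TSS200", "GENEA Body"))
  expect_true(ann$probes$enhancer[ann$probes$probe_id == "cg0001"])
  expect_true(ann$probes$intergenic[ann$probes$probe_id == "cg0002"])
  # duplicate (gene, region) pairs collapse to one
  expect_equal(sum(ann$assignments$probe_id == "cg0003"), 1)
})

test_that("annotation validation: length mismatch, synonyms, unknown labels", {
  expect_error(read_annotation(write_fixture_annotation(
    "cgX\t1\t5\tA;B\tTSS200\t")), "cgX")
  ann <- read_annotation(write_fixture_annotation(
    "cgY\t1\t5\tA;B\t5'UTR;3'UTR\tTRUE"))
  expect_setequal(ann$assignments$region, c("5UTR", "3UTR"))
  expect_error(read_annotation(write_fixture_annotation(
    "cgZ\t1\t5\tA\tPromoter\t")), "unknown region label")
  # manifest-style column aliases
  f <- tempfile()
  writeLines(c("IlmnID\tCHR\tMAPINFO\tUCSC_RefGene_Name\tUCSC_RefGene_Group\tEnhancer",
               "cg1\t7\t123\tG1\tBody\tTRUE"), f)
  ann2 <- read_annotation(f)
  expect_equal(ann2$assignments$gene, "G1")
  expect_true(ann2$probes$enhancer)
})

test_that("write_table renders re-readable TSV at 6 significant digits", {
  df <- data.frame(feature_id = c("a", "b"), effect = c(0.123456789, -1),
                   p_value = c(3.2e-7, 1), significant = c(TRUE, FALSE),
                   direction = c("up", "none"))
  f <- tempfile()
  write_table(df, f)
  back <- utils::read.delim(f)
  expect_equal(back$p_value[1], 3.2e-7, tolerance = 1e-12)
  expect_equal(back$effect[1], 0.123457, tolerance = 1e-9)
  expect_identical(back$direction, df$direction)
  expect_identical(back$significant, df$significant)
  # empty table writes a header-only file
  f2 <- tempfile()
  write_table(df[0, ], f2)
  expect_equal(length(readLines(f2)), 1)
  expect_equal(nrow(utils::read.delim(f2)), 0)
  # unwritable target errors with the path
  expect_error(write_table(df, file.path(tempfile(), "nodir", "x.tsv")),
               "nodir")
})

test_that("series-matrix reader extracts the value table", {
  f <- tempfile()
  writeLines(c("!Series_title\t\"x\"",
               "!series_matrix_table_begin",
               "ID_REF\tGSM1\tGSM2",
               "G1\t1.5\t2.5",
               "G2\t3\t4",
               "!series_matrix_table_end"), f)
  m <- read_series_matrix(f)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["G1", "GSM2"], 2.5)
})
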