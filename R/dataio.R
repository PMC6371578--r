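#' Canonical 450K gene-region labels
#'
#' The six probe location classes relative to a gene used throughout the
#' package, in manifest order: `TSS1500` (200-1500 bp upstream of the
#' transcription start site), `TSS200` (0-200 bp upstream), `5UTR`,
#' `1stExon`, `Body`, `3UTR`.
#'
#' @format Character vector of length 6.
#' @export
REGION_LABELS <- c("TSS1500", "TSS200", "5UTR", "1stExon", "Body", "3UTR")

# region synonyms accepted on input (manifest files use the primed forms)
.normalize_region <- function(x) {
  x <- sub("^5'UTR$", "5UTR", x)
  x <- sub("^3'UTR$", "3UTR", x)
  bad <- setdiff(unique(x), REGION_LABELS)
  if (length(bad) > 0)
    stop("unknown region label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  x
}

#' Construct a labeled feature-by-sample matrix
#'
#' A `labeled_matrix` carries a numeric matrix (features in rows, samples in
#' columns), the measurement scale, and per-sample case/control labels.  It is
#' the container for both log2 expression values and methylation beta values.
#'
#' @param values Numeric matrix with unique rownames (feature IDs) and
#'   colnames (sample IDs).
#' @param scale One of `"log2_expression"` or `"beta"`.  Beta values must lie
#'   in \[0, 1\]; values overshooting by no more than 1e-9 (a common artifact
#'   of background normalization) are clamped, anything further is rejected.
#' @param group Character or factor of per-sample labels, values in
#'   `{"case", "control"}`, length `ncol(values)`.
#' @param gender Optional per-sample labels in `{"male", "female", "unknown"}`.
#'
#' @return An object of class `labeled_matrix`: a list with elements
#'   `values`, `scale`, `group` (factor), `gender`.
#' @export
labeled_matrix <- function(values, scale = c("log2_expression", "beta"),
                           group, gender = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  fid <- rownames(values); sid <- colnames(values)
  if ((nrow(values) > 0 && is.null(fid)) || (ncol(values) > 0 && is.null(sid)))
    stop("'values' must have feature rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(fid))
    stop("duplicate feature IDs: ", paste(utils::head(fid[duplicated(fid)], 3), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sid))
    stop("duplicate sample IDs: ", paste(utils::head(sid[duplicated(sid)], 3), collapse = ", "),
         call. = FALSE)
  if (length(group) != ncol(values))
    stop("'group' must have one label per sample", call. = FALSE)
  group <- as.character(group)
  if (!all(group %in% c("case", "control")))
    stop("group labels must be 'case' or 'control'", call. = FALSE)
  if (scale == "beta") {
    v <- values[!is.na(values)]
    if (any(!is.finite(v)))
      stop("beta matrix contains non-finite values", call. = FALSE)
    lo <- v < 0; hi <- v > 1
    if (any(v[lo] < -1e-9) || any(v[hi] > 1 + 1e-9)) {
      bad <- which(is.na(values) | values < -1e-9 | values > 1 + 1e-9, arr.ind = TRUE)
      bad <- bad[!is.na(values[bad]), , drop = FALSE]
      stop(sprintf("beta value out of [0,1] at feature '%s', sample '%s'",
                   fid[bad[1, 1]], sid[bad[1, 2]]), call. = FALSE)
    }
    values[!is.na(values) & values < 0] <- 0
    values[!is.na(values) & values > 1] <- 1
  }
  if (!is.null(gender)) {
    if (length(gender) != ncol(values))
      stop("'gender' must have one label per sample", call. = FALSE)
    gender <- as.character(gender)
    if (!all(gender %in% c("male", "female", "unknown")))
      stop("gender labels must be 'male', 'female' or 'unknown'", call. = FALSE)
  }
  structure(list(values = values, scale = scale,
                 group = factor(group, levels = c("case", "control")),
                 gender = gender),
            class = "labeled_matrix")
}

#' @export
print.labeled_matrix <- function(x, ...) {
  cat(sprintf("labeled_matrix: %d features x %d samples (%s)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  groups: %d case, %d control\n",
              sum(x$group == "case"), sum(x$group == "control")))
  invisible(x)
}

#' @export
dim.labeled_matrix <- function(x) dim(x$values)

#' Read a feature-by-sample matrix with sample metadata
#'
#' Reads a TSV whose first column (header `ID`) holds feature identifiers and
#' whose remaining column headers are sample identifiers, plus a sidecar
#' metadata TSV with columns `sample_id`, `group` and optionally `gender`.
#'
#' @param path Path to the matrix TSV.
#' @param scale `"log2_expression"` or `"beta"` (see [labeled_matrix()]).
#' @param metadata Path to the metadata TSV, or a data frame with the same
#'   columns.  Every sample column must have a group label.
#' @param max_missing For beta matrices, probes missing in more than this
#'   fraction of samples are dropped (with a message); remaining missing
#'   values are carried as `NA` and excluded per-sample from region averages.
#'
#' @return A [labeled_matrix()].
#' @export
read_matrix <- function(path, scale = c("log2_expression", "beta"),
                        metadata, max_missing = 0.2) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("matrix file '", path, "' needs an ID column plus sample columns", call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicated feature ID '", ids[duplicated(ids)][1], "' in ", path, call. = FALSE)
  vals <- df[, -1, drop = FALSE]
  nonnum <- !vapply(vals, is.numeric, logical(1))
  if (any(nonnum))
    stop("non-numeric cells in column(s): ",
         paste(colnames(vals)[nonnum], collapse = ", "), " of ", path, call. = FALSE)
  m <- as.matrix(vals)
  rownames(m) <- ids
  meta <- if (is.data.frame(metadata)) metadata else read_metadata(metadata)
  missing_meta <- setdiff(colnames(m), meta$sample_id)
  if (length(missing_meta) > 0)
    stop("no group label for sample(s): ", paste(missing_meta, collapse = ", "), call. = FALSE)
  meta <- meta[match(colnames(m), meta$sample_id), ]
  if (scale == "beta" && anyNA(m)) {
    frac <- rowMeans(is.na(m))
    drop <- frac > max_missing
    if (any(drop)) {
      message(sum(drop), " probe(s) missing in >", round(100 * max_missing),
              "% of samples excluded")
      m <- m[!drop, , drop = FALSE]
    }
  }
  labeled_matrix(m, scale, meta$group,
                 gender = if ("gender" %in% names(meta)) meta$gender else NULL)
}

#' Read a sample metadata table
#'
#' @param path TSV with columns `sample_id`, `group` and optionally `gender`.
#' @return Data frame with those columns.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  if (!all(need %in% names(meta)))
    stop("metadata '", path, "' must have columns sample_id, group", call. = FALSE)
  meta$sample_id <- as.character(meta$sample_id)
  meta
}

#' Read a probe annotation table
#'
#' Parses a 450K-manifest-style annotation TSV.  Canonical columns are
#' `probe_id`, `chr`, `position`, `gene_names` (semicolon-separated),
#' `region_groups` (semicolon-separated, parallel to `gene_names`) and
#' `enhancer` (TRUE/FALSE/empty); the manifest aliases `IlmnID`, `CHR`,
#' `MAPINFO`, `UCSC_RefGene_Name`, `UCSC_RefGene_Group` and `Enhancer` are
#' accepted.  Parallel lists are expanded into (gene, region) pairs and
#' deduplicated; a probe with no gene assignment is intergenic.  Coordinates
#' are 1-based (manifest MAPINFO convention).
#'
#' @param path Path to the annotation TSV.
#' @return An object of class `probe_annotation`: list with `probes` (data
#'   frame: `probe_id`, `chr`, `position`, `enhancer`, `intergenic`) and
#'   `assignments` (data frame: `probe_id`, `gene`, `region`).
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA"))
  alias <- c(IlmnID = "probe_id", CHR = "chr", MAPINFO = "position",
             UCSC_RefGene_Name = "gene_names", UCSC_RefGene_Group = "region_groups",
             Enhancer = "enhancer")
  hit <- names(alias)[names(alias) %in% names(df)]
  names(df)[match(hit, names(df))] <- alias[hit]
  need <- c("probe_id", "chr", "position", "gene_names", "region_groups")
  if (!all(need %in% names(df)))
    stop("annotation '", path, "' missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  if (!"enhancer" %in% names(df)) df$enhancer <- FALSE
  probe_annotation(df)
}

#' Construct a probe annotation object from a data frame
#'
#' @param df Data frame with columns `probe_id`, `chr`, `position`,
#'   `gene_names`, `region_groups`, `enhancer` (see [read_annotation()]).
#' @return A `probe_annotation` object.
#' @export
probe_annotation <- function(df) {
  pid <- as.character(df$probe_id)
  if (anyDuplicated(pid))
    stop("duplicated probe ID '", pid[duplicated(pid)][1], "'", call. = FALSE)
  genes <- as.character(df$gene_names); genes[is.na(genes)] <- ""
  regs <- as.character(df$region_groups); regs[is.na(regs)] <- ""
  enh <- df$enhancer
  if (!is.logical(enh)) {
    enh <- toupper(trimws(as.character(enh)))
    enh <- !is.na(enh) & enh %in% c("TRUE", "T", "1", "YES")
  } else enh[is.na(enh)] <- FALSE

  gl <- strsplit(genes, ";", fixed = TRUE)
  rl <- strsplit(regs, ";", fixed = TRUE)
  ng <- lengths(gl); nr <- lengths(rl)
  if (any(ng != nr))
    stop("gene_names/region_groups length mismatch for probe '",
         pid[which(ng != nr)[1]], "'", call. = FALSE)
  idx <- rep.int(seq_along(pid), ng)
  assignments <- data.frame(probe_id = pid[idx],
                            gene = unlist(gl, use.names = FALSE),
                            region = .normalize_region(unlist(rl, use.names = FALSE)),
                            stringsAsFactors = FALSE)
  assignments <- unique(assignments)
  probes <- data.frame(probe_id = pid,
                       chr = as.character(df$chr),
                       position = as.integer(df$position),
                       enhancer = enh,
                       intergenic = ng == 0L,
                       stringsAsFactors = FALSE)
  structure(list(probes = probes, assignments = assignments),
            class = "probe_annotation")
}

#' @export
print.probe_annotation <- function(x, ...) {
  cat(sprintf("probe_annotation: %d probes (%d intergenic, %d enhancer), %d gene-region assignments\n",
              nrow(x$probes), sum(x$probes$intergenic), sum(x$probes$enhancer),
              nrow(x$assignments)))
  invisible(x)
}

#' Write a results table as TSV
#'
#' Writes any stage's result records (differential tables, dominant-region
#' calls, panel rows) with a stable column order, floats at 6 significant
#' digits, re-readable by [utils::read.delim()].
#'
#' @param records A data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records)) records <- as.data.frame(records)
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = 6, format = "g")
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("failed to write '", path, "': ", conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Extract the value table from a GEO series-matrix file
#'
#' Minimal reader: returns the numeric matrix between
#' `!series_matrix_table_begin` and `!series_matrix_table_end`.  Sample
#' characteristics lines are not parsed; group labels are supplied through the
#' sidecar metadata table (see [read_matrix()]).
#'
#' @param path Path to a series-matrix text file.
#' @return Numeric matrix, features in rows, samples in columns.
#' @export
read_series_matrix <- function(path) {
  lines <- readLines(path)
  b <- grep("^!series_matrix_table_begin", lines)
  e <- grep("^!series_matrix_table_end", lines)
  if (length(b) != 1 || length(e) != 1 || e <= b + 1)
    stop("no series-matrix table found in '", path, "'", call. = FALSE)
  df <- utils::read.delim(text = lines[(b + 1):(e - 1)], check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}
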