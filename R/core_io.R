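# Reading/writing count matrices and metadata, QC filtering, normalization.
#
# Count matrices are plain observations x genes matrices (base `matrix` or
# any Matrix class) with unique rownames (observation ids: cell barcodes or
# spot ids) and unique colnames (gene symbols). Two on-disk formats are
# supported: MatrixMarket triplets with sidecar barcode/gene label files, and
# dense TSV with a gene-id header row and an obs-id first column.

#' Read a count matrix
#'
#' @param path path to the matrix file: a MatrixMarket `.mtx` triplet file or
#'   a dense TSV (header row = gene ids, first column = observation ids).
#' @param format `"mtx"`, `"tsv"`, or `"auto"` (by file extension).
#' @param barcodes_file,genes_file label files for the `mtx` format, one id
#'   per line: observation ids for rows, gene ids for columns. Default to
#'   `barcodes.tsv` / `genes.tsv` next to `path`.
#' @return an observations x genes numeric matrix of non-negative integer
#'   counts with dimnames set.
#' @export
read_counts <- function(path, format = c("auto", "mtx", "tsv"),
                        barcodes_file = NULL, genes_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("count file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "tsv"
  }
  if (format == "mtx") {
    dir <- dirname(path)
    barcodes_file <- barcodes_file %||% file.path(dir, "barcodes.tsv")
    genes_file <- genes_file %||% file.path(dir, "genes.tsv")
    if (!file.exists(barcodes_file)) stop("missing barcodes label file: ", barcodes_file)
    if (!file.exists(genes_file)) stop("missing genes label file: ", genes_file)
    m <- as.matrix(Matrix::readMM(path))
    obs <- readLines(barcodes_file)
    genes <- readLines(genes_file)
    if (length(obs) != nrow(m)) {
      stop("barcodes file has ", length(obs), " ids but matrix has ", nrow(m), " rows")
    }
    if (length(genes) != ncol(m)) {
      stop("genes file has ", length(genes), " ids but matrix has ", ncol(m), " columns")
    }
    dimnames(m) <- list(obs, genes)
  } else {
    tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    obs <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(m) <- "numeric"
    rownames(m) <- obs
  }
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "invalid count (negative or non-integer) at observation '%s' (row %d), gene '%s': %s",
      rownames(m)[bad[1, 1]], bad[1, 1], colnames(m)[bad[1, 2]], m[bad[1, , drop = FALSE]]
    ))
  }
  check_counts(m)
  m
}

#' Write a count matrix
#'
#' Inverse of [read_counts()]; integer counts round-trip exactly in both
#' formats.
#'
#' @param counts observations x genes matrix with dimnames.
#' @param path output path (`.mtx` triplet or dense TSV).
#' @inheritParams read_counts
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = c("auto", "mtx", "tsv"),
                         barcodes_file = NULL, genes_file = NULL) {
  format <- match.arg(format)
  check_counts(counts)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "tsv"
  }
  if (format == "mtx") {
    dir <- dirname(path)
    barcodes_file <- barcodes_file %||% file.path(dir, "barcodes.tsv")
    genes_file <- genes_file %||% file.path(dir, "genes.tsv")
    Matrix::writeMM(methods::as(Matrix::Matrix(as_dense(counts), sparse = TRUE), "generalMatrix"), path)
    writeLines(rownames(counts), barcodes_file)
    writeLines(colnames(counts), genes_file)
  } else {
    m <- as_dense(counts)
    tab <- data.frame(obs_id = rownames(m), m, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write per-observation metadata
#'
#' Metadata is a TSV with columns `obs_id`, `sample_id`, `group` and
#' optionally `cell_type`, `x`, `y`, `layer`.
#'
#' @param path TSV path.
#' @return a data.frame.
#' @export
read_obs_meta <- function(path) {
  meta <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  check_meta(meta)
}

#' @rdname read_obs_meta
#' @param meta metadata data.frame.
#' @export
write_obs_meta <- function(meta, path) {
  check_meta(meta)
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Quality-control configuration
#'
#' Thresholds follow the conventions of droplet single-cell and bin-aggregated
#' spatial QC: observations are removed when the mitochondrial UMI fraction
#' strictly exceeds `max_mito_fraction`, when the number of detected genes is
#' strictly below `min_genes`, or (doublet rule, cells only) strictly above
#' `max_genes`. Observations exactly at a threshold are retained. Defaults are
#' the cell thresholds (10% mito, 500 genes, 6000-gene doublet cap); spot data
#' at bin200 resolution typically uses `qc_config(0.05, 200, NULL)` since a
#' spot legitimately aggregates several cells.
#'
#' @param max_mito_fraction maximum tolerated mitochondrial UMI fraction.
#' @param min_genes minimum number of detected genes.
#' @param max_genes doublet cap on detected genes, or `NULL` for none.
#' @param mito_prefix case-insensitive gene-symbol prefix identifying
#'   mitochondrial genes (default `"mt-"`, the mouse convention).
#' @return a `qc_config` list.
#' @export
qc_config <- function(max_mito_fraction = 0.10, min_genes = 500,
                      max_genes = 6000, mito_prefix = "mt-") {
  stopifnot(max_mito_fraction >= 0, max_mito_fraction <= 1, min_genes >= 0)
  if (!is.null(max_genes) && max_genes <= min_genes) {
    stop("max_genes must exceed min_genes")
  }
  structure(list(max_mito_fraction = max_mito_fraction, min_genes = min_genes,
                 max_genes = max_genes, mito_prefix = mito_prefix),
            class = "qc_config")
}

#' Filter low-quality observations
#'
#' Applies the three QC rules of [qc_config()] with strict inequalities.
#' The mitochondrial fraction is computed on raw UMI counts. If no gene
#' matches `mito_prefix` the mito rule is skipped and a warning is recorded
#' in the report.
#'
#' @param counts observations x genes count matrix.
#' @param cfg a [qc_config()].
#' @return list with `counts` (retained rows) and `report` (per-rule removal
#'   counts, totals, warnings, echoed parameters).
#' @export
qc_filter <- function(counts, cfg = qc_config()) {
  check_counts(counts)
  m <- as_dense(counts)
  warnings <- character()
  detected <- rowSums(m > 0)
  mito_idx <- grep(paste0("^", cfg$mito_prefix), colnames(m), ignore.case = TRUE)
  total <- rowSums(m)
  if (length(mito_idx) == 0) {
    warnings <- c(warnings, sprintf(
      "no genes match mito prefix '%s'; mitochondrial rule skipped", cfg$mito_prefix))
    mito_frac <- rep(0, nrow(m))
    fail_mito <- rep(FALSE, nrow(m))
  } else {
    mito_frac <- ifelse(total > 0, rowSums(m[, mito_idx, drop = FALSE]) / total, 0)
    fail_mito <- mito_frac > cfg$max_mito_fraction
  }
  fail_low <- detected < cfg$min_genes
  fail_high <- if (is.null(cfg$max_genes)) rep(FALSE, nrow(m)) else detected > cfg$max_genes
  keep <- !(fail_mito | fail_low | fail_high)
  report <- list(
    n_input = nrow(m),
    n_retained = sum(keep),
    n_removed = sum(!keep),
    removed_by_rule = c(mito = sum(fail_mito), low_genes = sum(fail_low),
                        doublet = sum(fail_high)),
    removed_ids = rownames(m)[!keep],
    warnings = warnings,
    params = unclass(cfg)
  )
  list(counts = counts[keep, , drop = FALSE], report = report)
}

#' Library-size normalize and log-transform counts
#'
#' `value(i, g) = log(1 + counts(i, g) * scale / total(i))`, the standard
#' counts-per-`scale` log transform (natural log, scale 10,000 by default).
#' Observations with zero total count map to all-zero rows.
#'
#' @param counts observations x genes count matrix.
#' @param scale library-size target (default 1e4).
#' @return a dense matrix of the same shape, with attribute
#'   `normalization = "log1p_cp<scale>"`.
#' @export
normalize_log1p <- function(counts, scale = 1e4) {
  check_counts(counts)
  m <- as_dense(counts)
  total <- rowSums(m)
  sf <- ifelse(total > 0, scale / total, 0)
  out <- log1p(m * sf)
  attr(out, "normalization") <- paste0("log1p_cp", format(scale, scientific = FALSE))
  out
}
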