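# Cell-type composition analysis: proportions, fold-change ranking, and
# observed/expected (Ro/e) chi-square enrichment.

#' Per-unit cell-type proportions
#'
#' @param meta metadata with `obs_id`, `cell_type` and the unit column.
#' @param by unit to tabulate over: `"sample"` (column `sample_id`) or
#'   `"group"`.
#' @return data.frame with the unit column, `group` (when `by = "sample"`),
#'   `cell_type`, `n` and `proportion`; proportions sum to 1 within each
#'   unit. Cell types absent from a unit appear with proportion 0.
#' @export
cell_proportions <- function(meta, by = c("sample", "group")) {
  by <- match.arg(by)
  meta <- check_meta(meta)
  if (is.null(meta$cell_type)) stop("metadata has no cell_type column")
  unit_col <- if (by == "sample") "sample_id" else "group"
  units <- unique(meta[[unit_col]])
  types <- sort(unique(meta$cell_type))
  out <- do.call(rbind, lapply(units, function(u) {
    sel <- meta[[unit_col]] == u
    if (!any(sel)) return(NULL)
    n <- table(factor(meta$cell_type[sel], levels = types))
    df <- data.frame(unit = u, cell_type = types, n = as.vector(n),
                     proportion = as.vector(n) / sum(n),
                     stringsAsFactors = FALSE)
    names(df)[1] <- unit_col
    if (by == "sample") df$group <- meta$group[sel][1]
    df
  }))
  rownames(out) <- NULL
  out
}

#' Rank cell types by old-versus-young proportion fold-change
#'
#' Per type, `log2((mean_old + pseudo) / (mean_young + pseudo))` where the
#' means are over per-sample proportions (samples are the replication unit,
#' not pooled cells). The pseudocount keeps types absent from one group
#' finite.
#'
#' @param meta metadata with `obs_id`, `sample_id`, `group`, `cell_type`.
#' @param pseudo pseudocount added to both group means.
#' @return data.frame with `cell_type`, `mean_old`, `mean_young`, `log2fc`,
#'   sorted by decreasing `log2fc`.
#' @export
log2fc_proportion <- function(meta, pseudo = 1e-4) {
  prop <- cell_proportions(meta, by = "sample")
  if (!all(c("young", "old") %in% prop$group)) {
    stop("both groups ('young', 'old') must be present")
  }
  types <- unique(prop$cell_type)
  out <- do.call(rbind, lapply(types, function(ct) {
    p <- prop[prop$cell_type == ct, ]
    mo <- mean(p$proportion[p$group == "old"])
    my <- mean(p$proportion[p$group == "young"])
    data.frame(cell_type = ct, mean_old = mo, mean_young = my,
               log2fc = log2((mo + pseudo) / (my + pseudo)),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$log2fc), ]
  rownames(out) <- NULL
  out
}

#' Ro/e enrichment of cell types in the old group
#'
#' For each cell type X within the stated universe, the cells are
#' cross-tabulated as (X / not-X) x (old / young) and tested with a Pearson
#' chi-square (df = 1, no continuity correction by default). Ro/e is the
#' observed number of X cells in the old group divided by the count expected
#' under independence (`old_total * type_total / grand_total`); values above
#' 1 indicate enrichment in the old group.
#'
#' @param meta metadata with `obs_id`, `group`, `cell_type`.
#' @param universe character vector of cell-type labels forming the
#'   comparison universe (e.g. all immune cell types). The universe is an
#'   explicit scientific choice, so it has no default; pass
#'   `unique(meta$cell_type)` to use every labelled cell.
#' @param correct apply Yates continuity correction (default `FALSE`).
#' @return data.frame per cell type with the 2x2 counts, `expected_old`,
#'   `roe`, `chi2`, `p`, BH-adjusted `p_adj`, and `reliable` (`FALSE` when
#'   any expected cell count is below 1, where the chi-square approximation
#'   is poor; the values are still reported).
#' @export
roe_enrichment <- function(meta, universe, correct = FALSE) {
  meta <- check_meta(meta)
  if (missing(universe) || is.null(universe)) {
    stop("'universe' must be given explicitly (e.g. unique(meta$cell_type))")
  }
  meta <- meta[meta$cell_type %in% universe, , drop = FALSE]
  if (!all(c("young", "old") %in% meta$group)) {
    stop("both groups ('young', 'old') must be non-empty within the universe")
  }
  grand <- nrow(meta)
  old_total <- sum(meta$group == "old")
  types <- intersect(universe, unique(meta$cell_type))
  out <- do.call(rbind, lapply(types, function(ct) {
    is_x <- meta$cell_type == ct
    is_old <- meta$group == "old"
    tab <- matrix(c(sum(is_x & is_old), sum(is_x & !is_old),
                    sum(!is_x & is_old), sum(!is_x & !is_old)),
                  2, 2, byrow = TRUE,
                  dimnames = list(c("X", "notX"), c("old", "young")))
    expected <- outer(rowSums(tab), colSums(tab)) / grand
    ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    data.frame(cell_type = ct,
               n_old_X = tab["X", "old"], n_young_X = tab["X", "young"],
               n_old_notX = tab["notX", "old"], n_young_notX = tab["notX", "young"],
               expected_old = expected["X", "old"],
               roe = tab["X", "old"] / expected["X", "old"],
               chi2 = unname(ht$statistic), p = ht$p.value,
               reliable = all(expected >= 1),
               stringsAsFactors = FALSE)
  }))
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
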