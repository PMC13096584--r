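# Differential expression: two-sided Wilcoxon rank-sum per gene with BH
# adjustment and threshold-based up/down calling, plus the three-way DEG
# intersection. The rank-sum engine is vectorized over genes and matches
# stats::wilcox.test(exact = FALSE, correct = TRUE), which serves as its
# oracle in the test suite.

# Vectorized two-sided rank-sum p-values: mat is observations x genes,
# idx_a/idx_b index the two groups. Normal approximation with tie correction
# and continuity correction.
rank_sum_p <- function(mat, idx_a, idx_b) {
  na <- length(idx_a)
  nb <- length(idx_b)
  n <- na + nb
  sub <- mat[c(idx_a, idx_b), , drop = FALSE]
  apply(sub, 2, function(v) {
    r <- rank(v)
    w <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    nt <- tabulate(match(v, v))
    nt <- nt[nt > 1]
    tie_term <- sum(nt^3 - nt)
    sigma2 <- (na * nb / 12) * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- w - na * nb / 2
    z <- z - sign(z) * 0.5
    min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
  })
}

#' Differential expression between two groups
#'
#' Per gene: `log2fc = log2((mean_a + eps) / (mean_b + eps))` on de-logged
#' normalized means (`expm1` of the log-normalized values), a two-sided
#' Wilcoxon rank-sum p-value, and BH adjustment across tested genes. A gene
#' is called `up` (in `group_a`) when `log2fc > lfc_thresh` and
#' `p_adj < padj_thresh`, `down` when `log2fc < -lfc_thresh` under the same
#' p cut, otherwise `ns`. The rank-sum test stands in for hurdle-model DE
#' engines; recovery of planted effects at the standard (|log2FC| > 1) and
#' lenient (> 0.25) thresholds is validated on synthetic data.
#'
#' @param norm observations x genes normalized matrix
#'   (see [normalize_log1p()]).
#' @param meta metadata with `obs_id` and the grouping column.
#' @param group_a,group_b labels in `group_col` to compare; `group_b = NULL`
#'   compares `group_a` against all other observations.
#' @param group_col grouping column name (default `"group"`).
#' @param lfc_thresh absolute log2 fold-change threshold (1 standard,
#'   0.25 lenient).
#' @param padj_thresh BH-adjusted p threshold.
#' @param eps pseudocount on the de-logged means.
#' @return data.frame per gene: `gene`, `log2fc`, `p`, `p_adj`, `pct_a`,
#'   `pct_b` (detection fractions), `direction`.
#' @export
de_test <- function(norm, meta, group_a, group_b = NULL, group_col = "group",
                    lfc_thresh = 1, padj_thresh = 0.05, eps = 1e-9) {
  norm <- as_dense(norm)
  meta <- check_meta(meta, rownames(norm))
  g <- meta[[group_col]]
  if (is.null(g)) stop("metadata has no column '", group_col, "'")
  idx_a <- which(g == group_a)
  idx_b <- if (is.null(group_b)) which(g != group_a) else which(g == group_b)
  if (length(idx_a) < 3 || length(idx_b) < 3) {
    stop("both groups need at least 3 observations (got ", length(idx_a),
         " and ", length(idx_b), ")")
  }
  expr <- expm1(norm)
  ma <- colMeans(expr[idx_a, , drop = FALSE])
  mb <- colMeans(expr[idx_b, , drop = FALSE])
  log2fc <- log2(ma + eps) - log2(mb + eps)  # difference form: swap negates exactly
  p <- rank_sum_p(norm, idx_a, idx_b)
  p_adj <- stats::p.adjust(p, method = "BH")
  direction <- rep("ns", ncol(norm))
  direction[log2fc > lfc_thresh & p_adj < padj_thresh] <- "up"
  direction[log2fc < -lfc_thresh & p_adj < padj_thresh] <- "down"
  out <- data.frame(gene = colnames(norm), log2fc = unname(log2fc),
                    p = unname(p), p_adj = unname(p_adj),
                    pct_a = unname(colMeans(norm[idx_a, , drop = FALSE] > 0)),
                    pct_b = unname(colMeans(norm[idx_b, , drop = FALSE] > 0)),
                    direction = direction, stringsAsFactors = FALSE)
  attr(out, "params") <- list(group_a = group_a,
                              group_b = group_b %||% "rest",
                              lfc_thresh = lfc_thresh,
                              padj_thresh = padj_thresh,
                              test = "wilcoxon_rank_sum")
  out
}

#' Three-way intersection of differentially expressed genes
#'
#' @param results list of exactly three [de_test()] results.
#' @return list with `up` (genes called up in all three) and `down` (genes
#'   called down in all three); the two sets are disjoint by construction.
#' @export
deg_intersect <- function(results) {
  if (length(results) != 3) stop("exactly three DE results are required")
  sets <- lapply(results, function(r) {
    list(up = r$gene[r$direction == "up"], down = r$gene[r$direction == "down"])
  })
  list(up = Reduce(intersect, lapply(sets, `[[`, "up")),
       down = Reduce(intersect, lapply(sets, `[[`, "down")))
}
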