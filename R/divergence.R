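# Transcriptomic divergence between groups: Bhattacharyya distance between
# Gaussian fits in a PCA embedding, estimated on repeated subsamples of equal
# size per group, and used to rank cell types by old-vs-young change.

#' PCA embedding of a normalized expression matrix
#'
#' Projects observations onto the leading principal components of the
#' centered, unit-scaled highly-variable genes (the top `n_hvg` by variance).
#' Component signs are fixed by making each component's largest-magnitude
#' gene loading positive, so the embedding is deterministic.
#'
#' @param norm observations x genes normalized matrix.
#' @param dims number of components (default 10).
#' @param n_hvg number of highly-variable genes used (default 2000, capped at
#'   the number of genes with positive variance).
#' @return observations x `dims` coordinate matrix.
#' @export
embed_pca <- function(norm, dims = 10, n_hvg = 2000) {
  norm <- as_dense(norm)
  if (nrow(norm) < dims + 1) stop("need at least dims + 1 observations")
  v <- apply(norm, 2, stats::var)
  usable <- names(v)[v > 0]
  if (length(usable) < dims) stop("fewer informative genes than requested dims")
  hvg <- usable[order(-v[usable], usable)][seq_len(min(n_hvg, length(usable)))]
  pc <- stats::prcomp(norm[, hvg, drop = FALSE], center = TRUE, scale. = TRUE,
                      rank. = dims)
  flip <- apply(pc$rotation, 2, function(w) sign(w[which.max(abs(w))]))
  flip[flip == 0] <- 1
  emb <- sweep(pc$x, 2, flip, `*`)
  rownames(emb) <- rownames(norm)
  emb
}

#' Bhattacharyya distance between two Gaussian-fitted samples
#'
#' Fits a multivariate Gaussian to each coordinate sample and evaluates the
#' closed form
#' \deqn{D = \frac{1}{8} (\mu_1-\mu_2)^\top \bar\Sigma^{-1} (\mu_1-\mu_2)
#'       + \frac{1}{2} \ln \frac{\det \bar\Sigma}
#'                              {\sqrt{\det \Sigma_1 \det \Sigma_2}},}
#' with \eqn{\bar\Sigma = (\Sigma_1+\Sigma_2)/2}. A ridge `ridge * I` is
#' added to each covariance for numerical stability at moderate sample
#' sizes. Identical samples give exactly 0; the distance is symmetric and
#' invariant under a common affine rotation of both samples.
#'
#' @param x1,x2 n x d coordinate matrices (or numeric vectors for d = 1).
#' @param ridge ridge added to each covariance diagonal.
#' @return non-negative scalar distance.
#' @export
bhattacharyya_gaussian <- function(x1, x2, ridge = 1e-6) {
  if (is.vector(x1)) x1 <- matrix(x1, ncol = 1)
  if (is.vector(x2)) x2 <- matrix(x2, ncol = 1)
  if (ncol(x1) != ncol(x2)) stop("samples must share dimensionality")
  d <- ncol(x1)
  mu1 <- colMeans(x1)
  mu2 <- colMeans(x2)
  s1 <- stats::cov(x1) + diag(ridge, d)
  s2 <- stats::cov(x2) + diag(ridge, d)
  sbar <- (s1 + s2) / 2
  delta <- mu1 - mu2
  # log-determinants via Cholesky: covariances + ridge are positive definite
  ldet <- function(s) 2 * sum(log(diag(chol(s))))
  dist <- as.numeric(delta %*% solve(sbar, delta)) / 8 +
    (ldet(sbar) - (ldet(s1) + ldet(s2)) / 2) / 2
  if (!is.finite(dist)) stop("non-finite Bhattacharyya distance (degenerate covariance)")
  dist
}

#' Subsampled per-cell-type divergence between groups
#'
#' For every cell type, draws `n_per_group` cells from each group
#' (without replacement when the group is large enough, otherwise with
#' replacement and flagged), computes the Gaussian Bhattacharyya distance in
#' the embedding, and repeats `reps` times. Cell types are ranked by the
#' median distance over repetitions.
#'
#' @param embedding observations x dims matrix from [embed_pca()].
#' @param meta metadata with `obs_id`, `group`, `cell_type`.
#' @param n_per_group cells drawn per group per repetition (default 250).
#' @param reps repetitions (default 100).
#' @param seed integer seed.
#' @param ridge passed to [bhattacharyya_gaussian()].
#' @return list of class `divergence_result`: `summary` (data.frame per cell
#'   type with `median`, `n_old`, `n_young`, `with_replacement`, ranked by
#'   decreasing median), `distances` (reps x types matrix), `n_per_group`,
#'   `reps`, `dims`. Types with an empty group are skipped with a warning.
#' @export
subsampled_divergence <- function(embedding, meta, n_per_group = 250,
                                  reps = 100, seed = NULL, ridge = 1e-6) {
  meta <- check_meta(meta, rownames(embedding))
  types <- sort(unique(meta$cell_type))
  with_seed(seed, {
    res <- lapply(types, function(ct) {
      idx_old <- which(meta$cell_type == ct & meta$group == "old")
      idx_young <- which(meta$cell_type == ct & meta$group == "young")
      if (!length(idx_old) || !length(idx_young)) {
        warning("cell type '", ct, "' empty in one group; skipped")
        return(NULL)
      }
      repl_old <- length(idx_old) < n_per_group
      repl_young <- length(idx_young) < n_per_group
      dists <- vapply(seq_len(reps), function(r) {
        so <- sample(idx_old, n_per_group, replace = repl_old)
        sy <- sample(idx_young, n_per_group, replace = repl_young)
        bhattacharyya_gaussian(embedding[so, , drop = FALSE],
                               embedding[sy, , drop = FALSE], ridge = ridge)
      }, 0)
      list(cell_type = ct, dists = dists,
           n_old = length(idx_old), n_young = length(idx_young),
           with_replacement = repl_old || repl_young)
    })
    res <- Filter(Negate(is.null), res)
    if (!length(res)) stop("no cell type has both groups populated")
    distances <- sapply(res, `[[`, "dists")
    colnames(distances) <- vapply(res, `[[`, "", "cell_type")
    summary <- data.frame(
      cell_type = colnames(distances),
      median = apply(distances, 2, stats::median),
      n_old = vapply(res, `[[`, 0L, "n_old"),
      n_young = vapply(res, `[[`, 0L, "n_young"),
      with_replacement = vapply(res, `[[`, FALSE, "with_replacement"),
      stringsAsFactors = FALSE)
    summary <- summary[order(-summary$median), ]
    rownames(summary) <- NULL
    structure(list(summary = summary, distances = distances,
                   n_per_group = n_per_group, reps = reps,
                   dims = ncol(embedding)),
              class = "divergence_result")
  })
}

#' @export
print.divergence_result <- function(x, ...) {
  cat("Subsampled Bhattacharyya divergence (", x$reps, " reps, n = ",
      x$n_per_group, "/group, ", x$dims, " dims)\n", sep = "")
  print(x$summary, ...)
  invisible(x)
}
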