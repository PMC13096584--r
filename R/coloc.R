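# Spatial colocalization analyses on spot-level cell-type abundances:
# per-layer density profiles, layer-grid density/proportion correlations,
# signature-score correlations, and a within-sample permutation test of
# spot-level colocalization.

#' Per-spot abundance proportions
#'
#' @param ab spots x cell-types non-negative density matrix.
#' @return matrix of per-spot proportions; rows with zero total density map
#'   to all-zero rows.
#' @export
abundance_proportions <- function(ab) {
  ab <- as_dense(ab)
  if (min(ab) < 0) stop("densities must be non-negative")
  total <- rowSums(ab)
  sweep(ab, 1, ifelse(total > 0, total, 1), `/`)
}

#' Mean density and proportion per (cell type, sample, layer)
#'
#' Aggregates a spot-level abundance matrix over the layer allocation. The
#' scaled variant z-scores each cell type's mean density across the whole
#' sample x layer grid (both groups together by default), matching how
#' layer-profile heatmaps are usually colored; zero-variance types scale
#' to 0.
#'
#' @param ab spots x cell-types density matrix (rownames = spot ids).
#' @param zn layer allocation from [assign_layers()]; every spot in `ab`
#'   must carry a layer.
#' @param meta metadata with `obs_id`, `sample_id`, `group`.
#' @param scale_within_group z-score within each group separately instead of
#'   across the full grid.
#' @return data.frame with `cell_type`, `sample_id`, `group`, `layer`,
#'   `mean_density`, `mean_proportion`, `scaled_density`.
#' @export
layer_profile <- function(ab, zn, meta, scale_within_group = FALSE) {
  ab <- as_dense(ab)
  missing_layer <- setdiff(rownames(ab), zn$obs_id)
  if (length(missing_layer)) {
    stop(length(missing_layer), " spot(s) in the abundance matrix have no ",
         "layer assignment")
  }
  meta <- check_meta(meta, rownames(ab))
  layer <- zn$layer[match(rownames(ab), zn$obs_id)]
  prop <- abundance_proportions(ab)
  key <- interaction(meta$sample_id, layer, drop = TRUE)
  cells <- split(seq_len(nrow(ab)), key)
  out <- do.call(rbind, lapply(cells, function(idx) {
    data.frame(cell_type = colnames(ab),
               sample_id = meta$sample_id[idx[1]],
               group = meta$group[idx[1]],
               layer = layer[idx[1]],
               mean_density = colMeans(ab[idx, , drop = FALSE]),
               mean_proportion = colMeans(prop[idx, , drop = FALSE]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  scale_unit <- if (scale_within_group) {
    interaction(out$cell_type, out$group, drop = TRUE)
  } else {
    out$cell_type
  }
  out$scaled_density <- stats::ave(out$mean_density, scale_unit, FUN = function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) return(rep(0, length(v)))
    (v - mean(v)) / s
  })
  out[order(out$cell_type, out$sample_id, out$layer), ]
}

#' Correlation of layer-profile densities between a focal type and others
#'
#' Pearson correlation over the (sample, layer) grid between the focal cell
#' type's mean density (or proportion) and each other type's, within an
#' optional group. The two-sided p-value comes from the t-distribution with
#' n - 2 degrees of freedom.
#'
#' @param profile output of [layer_profile()].
#' @param focal focal cell type.
#' @param others other cell types (default: all non-focal types in the
#'   profile).
#' @param mode correlate `"density"` or `"proportion"` values.
#' @param group restrict to one group, or `NULL` for all rows.
#' @return data.frame with `focal`, `other`, `r`, `p`, `n_points`, `note`
#'   (`NA` r with a reason when a vector has zero variance).
#' @export
density_correlation <- function(profile, focal, others = NULL,
                                mode = c("density", "proportion"),
                                group = NULL) {
  mode <- match.arg(mode)
  col <- paste0("mean_", mode)
  if (!is.null(group)) profile <- profile[profile$group == group, , drop = FALSE]
  types <- unique(profile$cell_type)
  if (!focal %in% types) stop("focal type '", focal, "' not in the profile")
  others <- others %||% setdiff(types, focal)
  grid_key <- function(df) paste(df$sample_id, df$layer)
  f <- profile[profile$cell_type == focal, ]
  if (nrow(f) < 3) stop("need at least 3 (sample, layer) points")
  out <- do.call(rbind, lapply(others, function(ot) {
    o <- profile[profile$cell_type == ot, ]
    o <- o[match(grid_key(f), grid_key(o)), ]
    x <- f[[col]]
    y <- o[[col]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(focal = focal, other = ot, r = NA_real_, p = NA_real_,
                        n_points = length(x), note = "zero variance",
                        stringsAsFactors = FALSE))
    }
    ht <- stats::cor.test(x, y, method = "pearson")
    data.frame(focal = focal, other = ot, r = unname(ht$estimate),
               p = ht$p.value, n_points = length(x), note = "",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Correlation between two signature scores across spots
#'
#' @param scores score matrix from [score_all()].
#' @param sig_a,sig_b signature column names.
#' @param spots optional subset of spot ids (e.g. one group's spots).
#' @param meta optional metadata; when given, per-sample correlations are
#'   appended to the pooled one.
#' @return data.frame with `sample_id` (`"all"` = pooled), `r`, `p`,
#'   `n_points`.
#' @export
score_correlation <- function(scores, sig_a, sig_b, spots = NULL, meta = NULL) {
  for (nm in c(sig_a, sig_b)) {
    if (!nm %in% colnames(scores)) stop("signature '", nm, "' not in score table")
  }
  if (!is.null(spots)) scores <- scores[rownames(scores) %in% spots, , drop = FALSE]
  if (nrow(scores) < 3) stop("need at least 3 spots")
  one <- function(idx, label) {
    ht <- stats::cor.test(scores[idx, sig_a], scores[idx, sig_b],
                          method = "pearson")
    data.frame(sample_id = label, r = unname(ht$estimate), p = ht$p.value,
               n_points = length(idx), stringsAsFactors = FALSE)
  }
  out <- one(seq_len(nrow(scores)), "all")
  if (!is.null(meta)) {
    meta <- check_meta(meta, rownames(scores))
    for (sid in unique(meta$sample_id)) {
      idx <- which(meta$sample_id == sid)
      if (length(idx) >= 3) out <- rbind(out, one(idx, sid))
    }
  }
  rownames(out) <- NULL
  out
}

# per-sample colocalization statistic between two density vectors
coloc_stat <- function(a, b, stat) {
  if (stat == "pearson") return(stats::cor(a, b))
  # min_product: overlap of the two spatial distributions, each normalized
  # to sum 1 within the sample
  sum(pmin(a / sum(a), b / sum(b)))
}

#' Permutation test of spatial colocalization between two cell types
#'
#' The observed colocalization score is the per-sample statistic between the
#' two types' spot densities (Pearson correlation by default), averaged
#' across samples. The null distribution is built by independently permuting
#' type B's densities across spots within each sample — preserving every
#' sample's density distribution while breaking the spatial pairing — and the
#' one-sided p-value uses the add-one rule
#' `p = (1 + #(null >= observed)) / (n_perm + 1)`, so it is never 0.
#'
#' @param ab spots x cell-types density matrix.
#' @param meta metadata with `obs_id`, `sample_id` (and `group` if you
#'   subset beforehand).
#' @param type_a,type_b cell-type columns to test.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @param stat `"pearson"` or `"min_product"`.
#' @return list of class `coloc_result`: `observed`, `per_sample_observed`,
#'   `p_perm`, `n_perm`, `null` (mean, sd, quantiles), `stat`,
#'   `excluded_samples`.
#' @export
permutation_coloc <- function(ab, meta, type_a, type_b, n_perm = 10000,
                              seed = NULL, stat = c("pearson", "min_product")) {
  stat <- match.arg(stat)
  ab <- as_dense(ab)
  for (nm in c(type_a, type_b)) {
    if (!nm %in% colnames(ab)) stop("cell type '", nm, "' not in abundance matrix")
  }
  meta <- check_meta(meta, rownames(ab))
  samples <- split(seq_len(nrow(ab)), meta$sample_id)
  excluded <- character()
  keep <- list()
  for (sid in names(samples)) {
    idx <- samples[[sid]]
    a <- ab[idx, type_a]
    b <- ab[idx, type_b]
    degenerate <- length(idx) < 3 ||
      (stat == "pearson" && (stats::sd(a) == 0 || stats::sd(b) == 0)) ||
      (stat == "min_product" && (sum(a) == 0 || sum(b) == 0))
    if (degenerate) {
      warning("sample '", sid, "' excluded (fewer than 3 spots or degenerate densities)")
      excluded <- c(excluded, sid)
    } else {
      keep[[sid]] <- idx
    }
  }
  if (!length(keep)) stop("no usable sample for the permutation test")

  per_sample_obs <- vapply(keep, function(idx) {
    coloc_stat(ab[idx, type_a], ab[idx, type_b], stat)
  }, 0)
  observed <- mean(per_sample_obs)

  null <- with_seed(seed, {
    acc <- matrix(0, n_perm, length(keep))
    for (k in seq_along(keep)) {
      idx <- keep[[k]]
      a <- ab[idx, type_a]
      b <- ab[idx, type_b]
      n <- length(idx)
      chunk <- max(1L, min(n_perm, as.integer(2e6 / n)))
      done <- 0L
      while (done < n_perm) {
        m <- min(chunk, n_perm - done)
        perm <- vapply(seq_len(m), function(j) b[sample.int(n)], numeric(n))
        acc[done + seq_len(m), k] <- if (stat == "pearson") {
          as.vector(stats::cor(a, perm))
        } else {
          ap <- a / sum(a)
          colSums(matrix(pmin(rep(ap, m), as.vector(perm) / sum(b)), n, m))
        }
        done <- done + m
      }
    }
    rowMeans(acc)
  })

  p_perm <- (1 + sum(null >= observed)) / (n_perm + 1)
  structure(list(
    type_a = type_a, type_b = type_b, stat = stat,
    observed = observed, per_sample_observed = per_sample_obs,
    p_perm = p_perm, n_perm = n_perm,
    null = list(mean = mean(null), sd = stats::sd(null),
                quantiles = stats::quantile(null, c(0.025, 0.5, 0.975))),
    excluded_samples = excluded), class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("Permutation colocalization: ", x$type_a, " ~ ", x$type_b,
      " (", x$stat, ")\n", sep = "")
  cat("  observed = ", format(x$observed, digits = 4),
      ", p_perm = ", format(x$p_perm, digits = 4),
      " (", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}
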