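# Gene-signature (module) scoring.
#
# A signature score for an observation is the mean normalized expression of
# the signature genes minus the mean over expression-matched control genes:
# genes are binned by dataset-wide average expression and, for every
# signature gene, control genes are drawn from its bin (excluding the
# signature itself), so the score is centered against genes of comparable
# abundance.

#' Construct a validated signature set
#'
#' @param sigs named list of character gene vectors.
#' @param mutually_disjoint if `TRUE`, enforce that no gene appears in two
#'   signatures (the convention for cell-type marker sets).
#' @return the list, classed `signature_set`.
#' @export
signature_set <- function(sigs, mutually_disjoint = FALSE) {
  if (length(sigs) && (is.null(names(sigs)) || any(!nzchar(names(sigs))))) {
    stop("signatures must be named")
  }
  if (anyDuplicated(names(sigs))) stop("duplicate signature names")
  for (nm in names(sigs)) {
    g <- sigs[[nm]]
    if (!length(g)) stop("signature '", nm, "' is empty")
    if (anyDuplicated(g)) stop("signature '", nm, "' has duplicate genes")
  }
  if (mutually_disjoint && length(sigs) > 1) {
    all_genes <- unlist(sigs, use.names = FALSE)
    dup <- unique(all_genes[duplicated(all_genes)])
    if (length(dup)) {
      stop("signatures are not mutually disjoint; shared genes: ",
           paste(utils::head(dup, 5), collapse = ", "))
    }
  }
  structure(sigs, class = "signature_set", mutually_disjoint = mutually_disjoint)
}

#' The six-gene CD8+ T-cell exhaustion signature
#'
#' Canonical exhaustion markers (mouse symbols): inhibitory receptors Pdcd1
#' (PD-1), Lag3, Tigit and Havcr2 (Tim-3), the exhaustion-programming
#' transcription factor Tox, and the chemokine Cxcl13.
#'
#' @return character vector of gene symbols.
#' @export
exhaustion_signature <- function() {
  c("Pdcd1", "Lag3", "Tigit", "Tox", "Havcr2", "Cxcl13")
}

#' Score one gene signature on all observations
#'
#' Genes are ranked by their dataset-wide average normalized expression
#' (ties broken by gene id, so binning is invariant to gene order) and split
#' into `nbins` near-equal bins. For each signature gene, up to `nctrl`
#' control genes are sampled without replacement from its bin, excluding all
#' signature genes; control draws are pooled across signature genes (a gene
#' may appear as control for several signature genes). The score of an
#' observation is the mean expression of the signature genes minus the mean
#' over the pooled control draws.
#'
#' On an observation-constant matrix the score is exactly 0, and adding a
#' constant to every gene of one observation leaves its score unchanged.
#'
#' @param norm observations x genes normalized expression matrix
#'   (see [normalize_log1p()]).
#' @param signature character vector of gene symbols; genes absent from
#'   `norm` are dropped with a warning.
#' @param nbins number of average-expression bins.
#' @param nctrl control genes drawn per signature gene.
#' @param seed integer seed for the control draws, or `NULL`.
#' @param exclude_zero_genes drop genes with zero total expression from the
#'   control pool and binning.
#' @param name signature name used in messages.
#' @return named numeric vector of per-observation scores.
#' @export
module_score <- function(norm, signature, nbins = 24, nctrl = 100,
                         seed = NULL, exclude_zero_genes = FALSE,
                         name = "signature") {
  norm <- as_dense(norm)
  genes <- colnames(norm)
  if (is.null(genes)) stop("normalized matrix must carry gene colnames")
  if (exclude_zero_genes) {
    keep <- colSums(norm) > 0
    norm <- norm[, keep, drop = FALSE]
    genes <- colnames(norm)
  }
  present <- intersect(signature, genes)
  if (!length(present)) {
    stop("all genes of signature '", name, "' are absent from the matrix")
  }
  if (length(present) < length(signature)) {
    warning(length(signature) - length(present), " gene(s) of signature '",
            name, "' absent from the matrix; dropped")
  }
  nbins <- min(nbins, length(genes))
  avg <- colMeans(norm)
  rank_pos <- integer(length(genes))
  rank_pos[order(avg, genes)] <- seq_along(genes)
  bin <- ceiling(rank_pos * nbins / length(genes))
  names(bin) <- genes

  ctrl <- with_seed(seed, {
    unlist(lapply(present, function(g) {
      pool <- genes[bin == bin[[g]]]
      pool <- setdiff(pool, signature)
      if (!length(pool)) return(character())
      sample(pool, min(nctrl, length(pool)))
    }), use.names = FALSE)
  })
  sig_mean <- rowMeans(norm[, present, drop = FALSE])
  if (!length(ctrl)) {
    warning("no control genes available for signature '", name,
            "'; score is the uncentered signature mean")
    return(sig_mean)
  }
  sig_mean - rowMeans(norm[, ctrl, drop = FALSE])
}

#' Score a set of signatures
#'
#' Applies [module_score()] to each signature; each signature's control draw
#' is seeded independently (derived from `seed` and the signature name), so
#' scores do not depend on signature order.
#'
#' @inheritParams module_score
#' @param sigs a [signature_set()] or named list of gene vectors.
#' @return observations x signatures numeric matrix (zero columns for an
#'   empty set).
#' @export
score_all <- function(norm, sigs, nbins = 24, nctrl = 100, seed = NULL,
                      exclude_zero_genes = FALSE) {
  if (!inherits(sigs, "signature_set")) sigs <- signature_set(sigs)
  if (isTRUE(attr(sigs, "mutually_disjoint"))) {
    signature_set(unclass(sigs), mutually_disjoint = TRUE)
  }
  norm <- as_dense(norm)
  out <- matrix(numeric(0), nrow(norm), 0,
                dimnames = list(rownames(norm), character()))
  for (nm in names(sigs)) {
    s <- module_score(norm, sigs[[nm]], nbins = nbins, nctrl = nctrl,
                      seed = if (is.null(seed)) NULL else stage_seed(seed, nm),
                      exclude_zero_genes = exclude_zero_genes, name = nm)
    out <- cbind(out, s)
    colnames(out)[ncol(out)] <- nm
  }
  out
}

#' Build disjoint top-N marker signatures per cell type
#'
#' For each label, genes are ranked by log2 fold-change of that label versus
#' all other observations (rank-sum p-value, then gene id, as tie-breaks) and
#' the `top_n` genes are retained. A gene claimed by more than one label is
#' assigned to the label where its fold-change is larger (lexicographic label
#' order on exact ties) and removed from the others, enforcing mutual
#' disjointness.
#'
#' @param norm observations x genes normalized matrix.
#' @param meta metadata with `obs_id` and the label column.
#' @param level name of the label column (default `"cell_type"`).
#' @param top_n genes retained per label before disjointness resolution.
#' @return a mutually disjoint [signature_set()]; labels with fewer than 3
#'   observations are excluded with a warning. The attribute `report` lists
#'   genes reassigned during overlap resolution.
#' @export
build_marker_signatures <- function(norm, meta, level = "cell_type",
                                    top_n = 30) {
  norm <- as_dense(norm)
  meta <- check_meta(meta, rownames(norm))
  labels <- meta[[level]]
  if (is.null(labels)) stop("metadata has no column '", level, "'")
  tab <- table(labels)
  small <- names(tab)[tab < 3]
  if (length(small)) {
    warning("label(s) with < 3 observations excluded: ",
            paste(small, collapse = ", "))
  }
  use <- setdiff(names(tab), small)
  if (length(use) < 2) stop("need at least 2 labels with >= 3 observations")

  ranked <- lapply(use, function(lb) {
    res <- de_test(norm, meta, group_a = lb, group_b = NULL,
                   group_col = level, lfc_thresh = 0)
    res <- res[order(-res$log2fc, res$p_adj, res$gene), ]
    utils::head(res[, c("gene", "log2fc")], top_n)
  })
  names(ranked) <- use

  # overlap resolution: larger fold-change wins, lexicographic label on ties
  claims <- do.call(rbind, lapply(use, function(lb) {
    data.frame(label = lb, ranked[[lb]], stringsAsFactors = FALSE)
  }))
  claims <- claims[order(claims$gene, -claims$log2fc, claims$label), ]
  winner <- claims[!duplicated(claims$gene), ]
  reassigned <- claims[duplicated(claims$gene), c("gene", "label")]
  sigs <- lapply(use, function(lb) {
    g <- ranked[[lb]]$gene
    g[g %in% winner$gene[winner$label == lb]]
  })
  names(sigs) <- use
  sigs <- sigs[vapply(sigs, length, 0L) > 0]
  out <- signature_set(sigs, mutually_disjoint = TRUE)
  attr(out, "report") <- list(excluded_labels = small,
                              dropped_claims = reassigned)
  out
}

#' Read / write signatures in GMT format
#'
#' GMT is tab-separated: signature name, description, then gene symbols.
#'
#' @param path GMT file path.
#' @return [read_gmt()]: a named list of gene vectors; [write_gmt()]: `path`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sigs <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 60))
    f[-(1:2)]
  })
  names(sigs) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sigs
}

#' @rdname read_gmt
#' @param sigs named list of gene vectors.
#' @param description description field written for each set.
#' @export
write_gmt <- function(sigs, path, description = "liverspatial") {
  lines <- vapply(names(sigs), function(nm) {
    paste(c(nm, description, sigs[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
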