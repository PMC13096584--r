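# Zonation scoring and per-sample layer allocation.
#
# Each spatial spot gets a region score = CV signature score - PV signature
# score (high = pericentral). Within each sample, spots are stratified into
# nine equal-count quantile layers by descending region score: layer 1 is the
# most CV-like, layer 9 the most PV-like; layers 1-3 form the CV zone, 4-6
# the intermediate zone, 7-9 the PV zone.

#' Per-spot region (zonation) score
#'
#' @param scores a score matrix from [score_all()] (observations x
#'   signatures).
#' @param cv_sig,pv_sig names of the CV and PV signature columns.
#' @return named numeric vector: CV score minus PV score per observation.
#' @export
region_score <- function(scores, cv_sig, pv_sig) {
  for (nm in c(cv_sig, pv_sig)) {
    if (!nm %in% colnames(scores)) {
      stop("signature '", nm, "' not present in the score table")
    }
  }
  stats::setNames(scores[, cv_sig] - scores[, pv_sig], rownames(scores))
}

# zone label from layer index, thirds of the layer range
layer_zone <- function(layer, n_layers) {
  cut_pts <- c(0, n_layers / 3, 2 * n_layers / 3, n_layers)
  c("CV", "mid", "PV")[findInterval(layer, cut_pts, left.open = TRUE,
                                    rightmost.closed = TRUE)]
}

#' Allocate spots to equal-count layers per sample
#'
#' Within each sample independently, spots are sorted by region score in
#' descending order (ties broken by observation id, so allocation is
#' deterministic) and partitioned into `n_layers` contiguous blocks whose
#' sizes differ by at most one; when the spot count is not a multiple of
#' `n_layers`, the larger blocks take the lower layer numbers. Layer 1 holds
#' the highest (most CV-like) scores. Because only the score order matters,
#' the allocation is invariant to any strictly increasing transform of the
#' scores.
#'
#' @param region_scores named numeric vector from [region_score()].
#' @param meta metadata with `obs_id` and `sample_id` covering all scored
#'   observations.
#' @param n_layers number of layers (default 9).
#' @return data.frame with `obs_id`, `sample_id`, `region_score`, `layer`
#'   (integer, 1 = most CV-like) and `zone` (`CV`/`mid`/`PV` by thirds of the
#'   layer range).
#' @export
assign_layers <- function(region_scores, meta, n_layers = 9) {
  if (is.null(names(region_scores))) stop("region scores must be named by obs_id")
  meta <- check_meta(meta, names(region_scores))
  out <- lapply(split(seq_along(region_scores), meta$sample_id), function(idx) {
    n <- length(idx)
    sid <- meta$sample_id[idx[1]]
    if (n < n_layers) {
      stop("sample '", sid, "' has ", n, " spots, fewer than ", n_layers,
           " layers")
    }
    s <- region_scores[idx]
    ord <- order(-s, names(s))
    sizes <- rep(n %/% n_layers, n_layers)
    extra <- n %% n_layers
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    layer <- integer(n)
    layer[ord] <- rep(seq_len(n_layers), sizes)
    data.frame(obs_id = names(s), sample_id = sid, region_score = unname(s),
               layer = layer, zone = layer_zone(layer, n_layers),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[match(names(region_scores), res$obs_id), ]
  rownames(res) <- NULL
  res
}
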