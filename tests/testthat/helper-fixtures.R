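# Shared fixture builders: everything is generated in code at test time.

# small named count matrix
toy_counts <- function(vals, obs = NULL, genes = NULL) {
  m <- as.matrix(vals)
  rownames(m) <- obs %||% paste0("obs", seq_len(nrow(m)))
  colnames(m) <- genes %||% paste0("g", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a fast spatial config: one small grid per sample unless overridden
fast_spatial_cfg <- function(...) {
  synth_config(grid_shape = c(10, 20), n_genes = 70, n_cv_markers = 20,
               n_pv_markers = 20, ...)
}

# a fast single-cell config
fast_sc_cfg <- function(...) {
  synth_config(sc_n_per_group = 400, sc_n_genes = 60, ...)
}

# closed-form Pearson chi-square oracle for a 2x2 table
chi2_oracle <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

# metadata frame for cells laid out as consecutive blocks of types
block_meta <- function(n_per_block, types, group = "young", sample_id = "s1") {
  n <- sum(n_per_block)
  data.frame(obs_id = paste0("c", seq_len(n)),
             sample_id = sample_id, group = group,
             cell_type = rep(types, n_per_block),
             stringsAsFactors = FALSE)
}
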