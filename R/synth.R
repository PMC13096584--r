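# Synthetic liver-lobule data generator.
#
# Emulates the statistical structure the downstream analyses assume, with
# serialized ground truth: spatial spots carrying a smooth latent
# central-vein (CV) -> portal-vein (PV) coordinate z in [0, 1] with
# zone-graded negative-binomial marker expression and per-type cell-abundance
# surfaces, and two-group single-cell data with known composition shifts and
# planted differentially expressed genes.

#' Configuration for the synthetic liver-lobule generator
#'
#' Defaults encode the study conditions validated by the package's tests:
#' two young and two old spatial samples on a 40 x 50 grid (2000 spots each);
#' 30 CV and 30 PV zonation markers with log-fold slope `zonation_beta` along
#' the latent axis; an exhausted-T-cell-like type (`Tex`) whose abundance is
#' PV-graded only in the old group, a PV-graded periportal hepatocyte, a
#' CV-graded pericentral hepatocyte and a spatially flat Kupffer-like type;
#' and single-cell data with 3000 cells per group, Tex at 12% of old vs 3% of
#' young cells, and five +2 log2-fold effect genes in old Tex cells.
#'
#' @param grid_shape `(rows, cols)` of the per-sample spot grid.
#' @param n_spots spots to take from the grid per sample; `NULL` uses the
#'   full grid. Must not exceed the grid capacity.
#' @param n_genes total genes in the spatial panel (zonation markers plus
#'   flat background genes).
#' @param n_cv_markers,n_pv_markers numbers of CV- and PV-graded marker genes.
#' @param zonation_beta log-fold expression slope per unit of the latent
#'   coordinate z: a CV marker has mean `base * exp(-beta * z)`, a PV marker
#'   `base * exp(+beta * z)`.
#' @param nb_dispersion negative-binomial overdispersion (variance =
#'   `mu + dispersion * mu^2`); `0` gives Poisson counts.
#' @param marker_base_mean geometric centre of the per-marker baseline count
#'   means; individual markers are log-spread over
#'   `marker_base_mean * 2^[-1, 1]` so they scatter across expression bins
#'   like real marker panels instead of sharing one average.
#' @param background_mean centre of the log-spaced spatially-constant count
#'   means given to background genes (spread over roughly
#'   `background_mean * 2^[-2, 4.5]`, covering the marker range so
#'   expression-matched control bins mix background genes with markers);
#'   also the mean of the two mitochondrial genes.
#' @param samples data.frame with columns `sample_id`, `group` describing the
#'   spatial samples.
#' @param cell_types named list; each element has `profile` in
#'   `c("pv_graded", "cv_graded", "flat")` and `amplitude`, a named vector of
#'   non-negative per-group amplitudes.
#' @param abundance_baseline flat density floor added to every type so that a
#'   type with amplitude 0 is present at noise level rather than identically
#'   absent.
#' @param abundance_noise_cv coefficient of variation of the multiplicative
#'   gamma noise applied to true densities (deconvolution-uncertainty
#'   stand-in).
#' @param sc_n_per_group single-cell dataset: cells per group.
#' @param sc_samples named list of per-group sample-id vectors (cells are
#'   assigned uniformly at random to samples within their group).
#' @param sc_compositions named list of per-group cell-type proportion
#'   vectors; each must sum to 1.
#' @param sc_effect data.frame with columns `cell_type`, `gene`, `log2fc`:
#'   genes whose mean is shifted by `2^log2fc` in old-group cells of that
#'   type.
#' @param sc_markers_per_type planted type-specific marker genes per type.
#' @param sc_n_genes total single-cell gene panel size.
#' @param sc_effect_base_mean,sc_marker_mean,sc_background_mean count means
#'   for effect genes (before shift), planted markers (in their own type) and
#'   background genes.
#' @param seed integer master seed; every draw flows from it.
#' @return a `synth_config` list.
#' @export
synth_config <- function(grid_shape = c(40L, 50L),
                         n_spots = NULL,
                         n_genes = 200L,
                         n_cv_markers = 30L,
                         n_pv_markers = 30L,
                         zonation_beta = 1,
                         nb_dispersion = 0.5,
                         marker_base_mean = 5,
                         background_mean = 1,
                         samples = data.frame(
                           sample_id = c("Y1", "Y2", "O1", "O2"),
                           group = c("young", "young", "old", "old"),
                           stringsAsFactors = FALSE),
                         cell_types = list(
                           Tex = list(profile = "pv_graded",
                                      amplitude = c(young = 0, old = 1)),
                           PP_hepatocyte = list(profile = "pv_graded",
                                                amplitude = c(young = 1, old = 1)),
                           PC_hepatocyte = list(profile = "cv_graded",
                                                amplitude = c(young = 1, old = 1)),
                           Kupffer = list(profile = "flat",
                                          amplitude = c(young = 1, old = 1))),
                         abundance_baseline = 0.1,
                         abundance_noise_cv = 0.1,
                         sc_n_per_group = 3000L,
                         sc_samples = list(young = c("Ys1", "Ys2", "Ys3"),
                                           old = c("Os1", "Os2", "Os3", "Os4")),
                         sc_compositions = list(
                           young = c(Tex = 0.03, CD8_T = 0.37, B = 0.30, Myeloid = 0.30),
                           old = c(Tex = 0.12, CD8_T = 0.28, B = 0.30, Myeloid = 0.30)),
                         sc_effect = data.frame(
                           cell_type = "Tex",
                           gene = paste0("EFF", 1:5),
                           log2fc = 2,
                           stringsAsFactors = FALSE),
                         sc_markers_per_type = 5L,
                         sc_n_genes = 100L,
                         sc_effect_base_mean = 2,
                         sc_marker_mean = 5,
                         sc_background_mean = 0.5,
                         seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape), n_spots = n_spots,
              n_genes = as.integer(n_genes),
              n_cv_markers = as.integer(n_cv_markers),
              n_pv_markers = as.integer(n_pv_markers),
              zonation_beta = zonation_beta, nb_dispersion = nb_dispersion,
              marker_base_mean = marker_base_mean,
              background_mean = background_mean,
              samples = samples, cell_types = cell_types,
              abundance_baseline = abundance_baseline,
              abundance_noise_cv = abundance_noise_cv,
              sc_n_per_group = as.integer(sc_n_per_group),
              sc_samples = sc_samples,
              sc_compositions = sc_compositions, sc_effect = sc_effect,
              sc_markers_per_type = as.integer(sc_markers_per_type),
              sc_n_genes = as.integer(sc_n_genes),
              sc_effect_base_mean = sc_effect_base_mean,
              sc_marker_mean = sc_marker_mean,
              sc_background_mean = sc_background_mean,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  stopifnot(length(cfg$grid_shape) == 2, all(cfg$grid_shape >= 1))
  if (cfg$n_cv_markers + cfg$n_pv_markers > cfg$n_genes) {
    stop("n_genes must accommodate all zonation markers")
  }
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (!all(c("sample_id", "group") %in% names(cfg$samples))) {
    stop("samples needs sample_id and group columns")
  }
  for (ct in names(cfg$cell_types)) {
    spec <- cfg$cell_types[[ct]]
    if (!spec$profile %in% c("pv_graded", "cv_graded", "flat")) {
      stop("unknown spatial profile for type ", ct, ": ", spec$profile)
    }
    if (any(spec$amplitude < 0)) stop("amplitudes must be >= 0 (type ", ct, ")")
  }
  invisible(cfg)
}

# NB draws parameterized by mean and overdispersion; dispersion 0 -> Poisson.
rcounts <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

# Spatial density profile on the latent coordinate z in [0, 1].
profile_fun <- function(profile, z) {
  switch(profile,
         pv_graded = stats::plogis(8 * (z - 0.5)),
         cv_graded = stats::plogis(-8 * (z - 0.5)),
         flat = rep(1, length(z)),
         stop("unknown profile: ", profile))
}

#' Simulate a zonated spatial transcriptomics dataset
#'
#' Each sample is a spot grid carrying a smooth latent zonation coordinate
#' `z` (0 = CV, 1 = PV) that oscillates sinusoidally across grid columns over
#' two full periods, so every sample spans both zones repeatedly, as lobules
#' tile a liver section. CV/PV marker genes have log-linear mean expression in
#' `z` with slope `zonation_beta`; background genes are flat. Counts are
#' negative-binomial. Per-type true abundance surfaces follow the configured
#' spatial profiles scaled by per-group amplitudes on top of a flat baseline;
#' the returned abundance matrix adds multiplicative gamma noise, standing in
#' for the uncertainty of an external deconvolution.
#'
#' @param cfg a [synth_config()].
#' @return list with `counts` (spots x genes), `meta` (obs_id, sample_id,
#'   group, x, y), `abundance` (spots x cell types, noisy), and `truth`
#'   (latent `z` per spot, noise-free `true_abundance`, marker gene lists and
#'   echoed parameters).
#' @export
simulate_spatial <- function(cfg = synth_config()) {
  validate_synth_config(cfg)
  rows <- cfg$grid_shape[1]
  cols <- cfg$grid_shape[2]
  capacity <- rows * cols
  n_spots <- cfg$n_spots %||% capacity
  if (n_spots > capacity) {
    stop("grid ", rows, "x", cols, " too small for ", n_spots, " spots")
  }
  n_bg <- cfg$n_genes - cfg$n_cv_markers - cfg$n_pv_markers
  if (n_bg < 0) stop("n_genes must accommodate all zonation markers")
  # the first two background genes are mitochondrial so the QC mito rule has
  # something to act on; they behave like flat background otherwise
  bg_names <- if (n_bg > 0) sprintf("BG%03d", seq_len(n_bg)) else character()
  if (n_bg >= 2) bg_names[1:2] <- c("mt-Nd1", "mt-Co1")
  genes <- c(sprintf("CVmark%02d", seq_len(cfg$n_cv_markers)),
             sprintf("PVmark%02d", seq_len(cfg$n_pv_markers)),
             bg_names)
  types <- names(cfg$cell_types)

  with_seed(cfg$seed, {
    per_sample <- lapply(seq_len(nrow(cfg$samples)), function(si) {
      sid <- cfg$samples$sample_id[si]
      grp <- cfg$samples$group[si]
      grid <- expand.grid(y = seq_len(rows), x = seq_len(cols))[seq_len(n_spots), ]
      # two full sinusoidal periods across columns: z sweeps CV->PV->CV twice
      z <- 0.5 - 0.5 * cos(2 * pi * 2 * (grid$x - 1) / max(cols - 1, 1))
      obs <- sprintf("%s_spot%04d", sid, seq_len(n_spots))

      # Baseline levels emulate the broad mean-expression distribution of
      # real panels: each marker gene gets its own log-spread baseline and
      # background genes span a wider log-spaced range, so the
      # average-expression bins used for control-gene matching mix markers
      # with spatially flat genes. The two mitochondrial genes sit at the
      # background centre level. Abundance noise is drawn from its own
      # seeded stream so the spatial surfaces do not depend on the gene
      # panel configuration.
      bg_mu <- rep(cfg$background_mean, n_bg)
      if (n_bg > 2) {
        bg_mu[-(1:2)] <- cfg$background_mean * 2^seq(-2, 4.5,
                                                     length.out = n_bg - 2)
      }
      marker_base <- function(k) {
        if (k == 1) return(cfg$marker_base_mean)
        cfg$marker_base_mean * 2^seq(-1, 1, length.out = k)
      }
      mu <- matrix(rep(c(numeric(cfg$n_cv_markers + cfg$n_pv_markers), bg_mu),
                       each = n_spots),
                   n_spots, cfg$n_genes, dimnames = list(obs, genes))
      cv_idx <- seq_len(cfg$n_cv_markers)
      pv_idx <- cfg$n_cv_markers + seq_len(cfg$n_pv_markers)
      mu[, cv_idx] <- outer(exp(-cfg$zonation_beta * z),
                            marker_base(cfg$n_cv_markers))
      mu[, pv_idx] <- outer(exp(cfg$zonation_beta * z),
                            marker_base(cfg$n_pv_markers))
      set.seed(stage_seed(cfg$seed, paste0("counts_", sid)))
      counts <- matrix(rcounts(length(mu), as.vector(mu), cfg$nb_dispersion),
                       n_spots, cfg$n_genes, dimnames = dimnames(mu))

      true_ab <- sapply(types, function(ct) {
        spec <- cfg$cell_types[[ct]]
        amp <- spec$amplitude[[grp]]
        cfg$abundance_baseline + amp * profile_fun(spec$profile, z)
      })
      rownames(true_ab) <- obs
      noise <- if (cfg$abundance_noise_cv > 0) {
        shp <- 1 / cfg$abundance_noise_cv^2
        set.seed(stage_seed(cfg$seed, paste0("abundance_", sid)))
        matrix(stats::rgamma(length(true_ab), shape = shp, rate = shp),
               nrow(true_ab), ncol(true_ab))
      } else {
        1
      }
      list(counts = counts,
           meta = data.frame(obs_id = obs, sample_id = sid, group = grp,
                             x = grid$x, y = grid$y, stringsAsFactors = FALSE),
           abundance = true_ab * noise,
           true_abundance = true_ab,
           z = stats::setNames(z, obs))
    })

    truth <- list(
      z = do.call(c, lapply(per_sample, `[[`, "z")),
      true_abundance = do.call(rbind, lapply(per_sample, `[[`, "true_abundance")),
      cv_markers = genes[seq_len(cfg$n_cv_markers)],
      pv_markers = genes[cfg$n_cv_markers + seq_len(cfg$n_pv_markers)],
      background_genes = if (n_bg > 0) genes[cfg$n_cv_markers + cfg$n_pv_markers + seq_len(n_bg)] else character(),
      cell_types = types,
      params = list(zonation_beta = cfg$zonation_beta,
                    nb_dispersion = cfg$nb_dispersion,
                    abundance_baseline = cfg$abundance_baseline,
                    abundance_noise_cv = cfg$abundance_noise_cv,
                    amplitudes = lapply(cfg$cell_types, `[[`, "amplitude"),
                    profiles = vapply(cfg$cell_types, `[[`, "", "profile"))
    )
    list(counts = do.call(rbind, lapply(per_sample, `[[`, "counts")),
         meta = do.call(rbind, lapply(per_sample, `[[`, "meta")),
         abundance = do.call(rbind, lapply(per_sample, `[[`, "abundance")),
         truth = truth)
  })
}

#' Simulate a two-group single-cell dataset
#'
#' Cells are drawn per group with multinomial cell-type composition
#' `sc_compositions` and assigned uniformly to that group's samples. Each
#' type's gene means are shared across groups except the configured effect
#' genes, which are shifted by `2^log2fc` in the old group; each type also
#' carries planted high-expression marker genes. Counts are
#' negative-binomial.
#'
#' @param cfg a [synth_config()].
#' @return list with `counts` (cells x genes), `meta` (obs_id, sample_id,
#'   group, cell_type) and `truth` (group compositions, effect-gene table,
#'   per-type marker lists).
#' @export
simulate_single_cell <- function(cfg = synth_config()) {
  validate_synth_config(cfg)
  comps <- cfg$sc_compositions
  groups <- names(comps)
  types <- names(comps[[1]])
  for (g in groups) {
    if (abs(sum(comps[[g]]) - 1) > 1e-9) {
      stop("composition vector for group '", g, "' does not sum to 1")
    }
    if (!identical(names(comps[[g]]), types)) {
      stop("composition vectors must share cell-type names and order")
    }
  }

  marker_genes <- stats::setNames(lapply(types, function(ct) {
    sprintf("%s_mark%d", ct, seq_len(cfg$sc_markers_per_type))
  }), types)
  effect_genes <- unique(cfg$sc_effect$gene)
  fixed <- c(unlist(marker_genes, use.names = FALSE), effect_genes)
  if (anyDuplicated(fixed)) stop("marker and effect gene names must be disjoint")
  n_bg <- cfg$sc_n_genes - length(fixed)
  if (n_bg < 0) stop("sc_n_genes too small for markers plus effect genes")
  genes <- c(fixed, if (n_bg > 0) sprintf("SCBG%03d", seq_len(n_bg)))

  # baseline mean per (type, gene): background everywhere, markers high in
  # their own type, effect genes at their base mean before any group shift
  base_mu <- matrix(cfg$sc_background_mean, length(types), length(genes),
                    dimnames = list(types, genes))
  for (ct in types) base_mu[ct, marker_genes[[ct]]] <- cfg$sc_marker_mean
  base_mu[, effect_genes] <- cfg$sc_effect_base_mean

  with_seed(cfg$seed, {
    out <- lapply(groups, function(g) {
      n <- cfg$sc_n_per_group
      n_per_type <- as.vector(stats::rmultinom(1, n, comps[[g]]))
      cell_type <- rep(types, n_per_type)
      obs <- sprintf("%s_cell%05d", g, seq_len(n))
      sample_id <- sample(cfg$sc_samples[[g]], n, replace = TRUE)
      counts <- matrix(0L, n, length(genes), dimnames = list(obs, genes))
      for (ct in types) {
        idx <- which(cell_type == ct)
        if (!length(idx)) next
        mu <- base_mu[ct, ]
        if (g == "old") {
          eff <- cfg$sc_effect[cfg$sc_effect$cell_type == ct, , drop = FALSE]
          if (nrow(eff)) mu[eff$gene] <- mu[eff$gene] * 2^eff$log2fc
        }
        counts[idx, ] <- rcounts(length(idx) * length(genes),
                                 rep(mu, each = length(idx)),
                                 cfg$nb_dispersion)
      }
      list(counts = counts,
           meta = data.frame(obs_id = obs, sample_id = sample_id, group = g,
                             cell_type = cell_type, stringsAsFactors = FALSE))
    })
    truth <- list(group_compositions = comps,
                  effect_genes = cfg$sc_effect,
                  marker_genes = marker_genes,
                  params = list(nb_dispersion = cfg$nb_dispersion,
                                n_per_group = cfg$sc_n_per_group))
    list(counts = do.call(rbind, lapply(out, `[[`, "counts")),
         meta = do.call(rbind, lapply(out, `[[`, "meta")),
         truth = truth)
  })
}

#' Serialize generator ground truth to JSON
#'
#' @param truth the `truth` element of [simulate_spatial()] or
#'   [simulate_single_cell()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_synth_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
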