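test_that("the generator is deterministic given a seed", {
  cfg <- fast_spatial_cfg(seed = 11)
  a <- simulate_spatial(cfg)
  b <- simulate_spatial(cfg)
  expect_identical(a, b)
  sc1 <- simulate_single_cell(fast_sc_cfg(seed = 11))
  sc2 <- simulate_single_cell(fast_sc_cfg(seed = 11))
  expect_identical(sc1, sc2)
  # and a different seed actually changes the draws
  expect_false(identical(a$counts, simulate_spatial(fast_spatial_cfg(seed = 12))$counts))
})

test_that("zonation_beta = 0 flattens CV and PV marker means", {
  cfg <- synth_config(grid_shape = c(40, 50), n_genes = 50, n_cv_markers = 20,
                      n_pv_markers = 20, zonation_beta = 0, seed = 3,
                      samples = data.frame(sample_id = "S1", group = "old"))
  sim <- simulate_spatial(cfg)
  z <- sim$truth$z
  cv_mean_lo <- mean(sim$counts[z < 0.5, sim$truth$cv_markers])
  cv_mean_hi <- mean(sim$counts[z >= 0.5, sim$truth$cv_markers])
  # 2000 spots x 20 markers; mean difference within 3 standard errors of 0
  n_lo <- sum(z < 0.5) * 20
  se <- sqrt(var(as.vector(sim$counts[, sim$truth$cv_markers])) * 2 / n_lo)
  expect_lt(abs(cv_mean_lo - cv_mean_hi), 3 * se)
  pv_lo <- mean(sim$counts[z < 0.5, sim$truth$pv_markers])
  pv_hi <- mean(sim$counts[z >= 0.5, sim$truth$pv_markers])
  expect_lt(abs(pv_lo - pv_hi), 3 * se)
})

test_that("group amplitudes drive the true abundance surfaces", {
  cfg <- fast_spatial_cfg(seed = 4)
  sim <- simulate_spatial(cfg)
  old <- sim$meta$group == "old"
  # Tex: pv_graded with amplitude old = 1, young = 0
  expect_gt(mean(sim$truth$true_abundance[old, "Tex"]),
            mean(sim$truth$true_abundance[!old, "Tex"]))
  # graded types track z in the stated direction
  z <- sim$truth$z
  expect_gt(cor(z[old], sim$truth$true_abundance[old, "PP_hepatocyte"]), 0.9)
  expect_lt(cor(z[old], sim$truth$true_abundance[old, "PC_hepatocyte"]), -0.9)
  expect_true(all(sim$abundance >= 0))
  expect_true(all(sim$truth$z >= 0 & sim$truth$z <= 1))
})

test_that("grid capacity and composition sanity checks error", {
  expect_error(simulate_spatial(fast_spatial_cfg(n_spots = 10 * 20 + 1)),
               "too small")
  bad <- fast_sc_cfg()
  bad$sc_compositions$young["Tex"] <- 0.5
  expect_error(simulate_single_cell(bad), "sum to 1")
})

test_that("generated counts match the negative-binomial mean/variance", {
  # one flat type, one group: counts are iid NB(mu, dispersion)
  cfg <- synth_config(grid_shape = c(50, 50), n_genes = 4, n_cv_markers = 1,
                      n_pv_markers = 1, zonation_beta = 0, nb_dispersion = 0.5,
                      marker_base_mean = 4, background_mean = 4, seed = 9,
                      samples = data.frame(sample_id = "S1", group = "old"))
  sim <- simulate_spatial(cfg)
  x <- as.vector(sim$counts)  # 10^4 draws, all mean 4
  mu <- 4
  v <- mu + 0.5 * mu^2
  expect_equal(mean(x), mu, tolerance = 3 * sqrt(v / length(x)) / mu)
  # variance within Monte-Carlo error (fourth-moment based SE, 4 sigma)
  se_var <- sqrt((mean((x - mean(x))^4) - v^2) / length(x))
  expect_lt(abs(var(x) - v), 4 * se_var)
})

test_that("realized composition shifts match binomial sampling", {
  cfg <- synth_config(sc_n_per_group = 2000, sc_n_genes = 40,
                      sc_markers_per_type = 2,
                      sc_compositions = list(
                        young = c(Tex = 0.10, CD8_T = 0.40, B = 0.25, Myeloid = 0.25),
                        old = c(Tex = 0.30, CD8_T = 0.20, B = 0.25, Myeloid = 0.25)),
                      seed = 21)
  sim <- simulate_single_cell(cfg)
  p_old <- mean(sim$meta$cell_type[sim$meta$group == "old"] == "Tex")
  p_young <- mean(sim$meta$cell_type[sim$meta$group == "young"] == "Tex")
  # 99% binomial CI bounds on each group proportion, propagated to the ratio
  ci_old <- qbinom(c(0.005, 0.995), 2000, 0.30) / 2000
  ci_young <- qbinom(c(0.005, 0.995), 2000, 0.10) / 2000
  expect_gt(p_old / p_young, ci_old[1] / ci_young[2])
  expect_lt(p_old / p_young, ci_old[2] / ci_young[1])
})

test_that("serialized truth is sufficient to recheck the generator", {
  d <- withr::local_tempdir()
  sim <- simulate_spatial(fast_spatial_cfg(seed = 2))
  path <- write_synth_truth(sim$truth, file.path(d, "truth.json"))
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(unname(unlist(back$z)), unname(sim$truth$z), tolerance = 1e-12)
  expect_identical(back$cv_markers, sim$truth$cv_markers)
  expect_equal(back$params$zonation_beta, 1)
})
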