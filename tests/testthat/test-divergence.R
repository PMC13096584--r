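test_that("PCA embedding is deterministic with ordered variances", {
  set.seed(4)
  norm <- toy_counts(matrix(rnorm(60 * 30, 5), 60, 30))
  emb <- embed_pca(norm, dims = 5)
  expect_identical(emb, embed_pca(norm, dims = 5))
  v <- apply(emb, 2, var)
  expect_true(all(diff(v) <= 1e-12))
  # duplicated observation maps to identical coordinates
  norm2 <- rbind(norm, dup = norm[1, ])
  rownames(norm2)[61] <- "dup"
  emb2 <- embed_pca(norm2, dims = 5)
  expect_equal(unname(emb2["dup", ]), unname(emb2[1, ]), tolerance = 1e-10)
})

test_that("planar data is captured exactly by two components", {
  set.seed(11)
  latent <- matrix(rnorm(200), 100, 2)
  load <- matrix(rnorm(12), 2, 6)
  norm <- toy_counts(latent %*% load)
  emb <- embed_pca(norm, dims = 2)
  # reconstructing the (scaled, centered) data from 2 PCs leaves no residual
  x <- scale(norm)
  pc <- prcomp(x, center = FALSE, scale. = FALSE)
  recon_err <- sum((x - pc$x[, 1:2] %*% t(pc$rotation[, 1:2]))^2)
  expect_lt(recon_err, 1e-18 * sum(x^2) + 1e-12)
  expect_equal(dim(emb), c(100, 2))
  expect_error(embed_pca(norm[1:2, ], dims = 5), "observations")
})

test_that("Bhattacharyya distance honors identity, symmetry, positivity", {
  set.seed(21)
  x <- matrix(rnorm(500), 100, 5)
  y <- matrix(rnorm(500, 1), 100, 5)
  expect_identical(bhattacharyya_gaussian(x, x), 0)
  expect_equal(bhattacharyya_gaussian(x, y), bhattacharyya_gaussian(y, x),
               tolerance = 1e-12)
  expect_gt(bhattacharyya_gaussian(x, y), 0)
})

test_that("the Gaussian closed form is recovered on 1-D shifted normals", {
  set.seed(31)
  x <- rnorm(1e5, 0, 1)
  y <- rnorm(1e5, 2, 1)
  # equal variances: D = (1/8) * delta_mu^2 / sigma^2 = 0.5
  expect_equal(bhattacharyya_gaussian(x, y), 0.5, tolerance = 0.02)
})

test_that("distance is invariant under a common rotation", {
  set.seed(41)
  x <- matrix(rnorm(300), 100, 3)
  y <- matrix(rnorm(300, 0.5), 100, 3)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))  # random orthogonal matrix
  d0 <- bhattacharyya_gaussian(x, y)
  d1 <- bhattacharyya_gaussian(x %*% q, y %*% q)
  expect_equal(d0, d1, tolerance = 1e-8)
})

test_that("subsampled divergence is seeded and ranks a planted shift on top", {
  set.seed(51)
  n <- 400
  emb <- matrix(rnorm(4 * n * 3), 4 * n, 3)
  meta <- data.frame(obs_id = paste0("c", seq_len(4 * n)),
                     sample_id = "s", group = rep(c("old", "young"), each = 2 * n),
                     cell_type = rep(rep(c("T", "B"), each = n), 2),
                     stringsAsFactors = FALSE)
  rownames(emb) <- meta$obs_id
  emb[meta$cell_type == "T" & meta$group == "old", 1] <-
    emb[meta$cell_type == "T" & meta$group == "old", 1] + 2
  dv <- subsampled_divergence(emb, meta, n_per_group = 100, reps = 20, seed = 7)
  expect_identical(dv$summary$cell_type[1], "T")
  expect_true(all(dv$distances >= 0))
  expect_equal(dim(dv$distances), c(20, 2))
  dv2 <- subsampled_divergence(emb, meta, n_per_group = 100, reps = 20, seed = 7)
  expect_identical(dv$distances, dv2$distances)
})

test_that("median divergence increases with the planted shift size", {
  set.seed(61)
  n <- 300
  base <- matrix(rnorm(2 * n * 3), 2 * n, 3)
  meta <- data.frame(obs_id = paste0("c", seq_len(2 * n)), sample_id = "s",
                     group = rep(c("old", "young"), each = n), cell_type = "T",
                     stringsAsFactors = FALSE)
  med <- sapply(c(0, 1, 2, 4), function(shift) {
    emb <- base
    rownames(emb) <- meta$obs_id
    emb[meta$group == "old", 1] <- emb[meta$group == "old", 1] + shift
    subsampled_divergence(emb, meta, n_per_group = 150, reps = 15,
                          seed = 3)$summary$median
  })
  expect_true(all(diff(med) > 0))
})

test_that("small groups fall back to replacement sampling, flagged", {
  set.seed(71)
  emb <- matrix(rnorm(60 * 2), 60, 2)
  meta <- data.frame(obs_id = paste0("c", 1:60), sample_id = "s",
                     group = rep(c("old", "young"), c(50, 10)), cell_type = "T",
                     stringsAsFactors = FALSE)
  rownames(emb) <- meta$obs_id
  dv <- subsampled_divergence(emb, meta, n_per_group = 30, reps = 5, seed = 1)
  expect_true(dv$summary$with_replacement)
  # a type empty in one group is skipped with a warning
  meta2 <- meta
  meta2$cell_type[meta2$group == "young"][1:5] <- "onlyYoung"
  expect_warning(dv2 <- subsampled_divergence(emb, meta2, n_per_group = 5,
                                              reps = 3, seed = 1), "onlyYoung")
  expect_identical(dv2$summary$cell_type, "T")
})
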