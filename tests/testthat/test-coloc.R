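make_layers <- function(meta, n_layers = 9) {
  # simple deterministic layer allocation from spot order within sample
  do.call(rbind, lapply(split(meta, meta$sample_id), function(m) {
    n <- nrow(m)
    data.frame(obs_id = m$obs_id, sample_id = m$sample_id,
               region_score = rev(seq_len(n)),
               layer = as.integer(cut(seq_len(n), n_layers, labels = FALSE)),
               zone = NA, stringsAsFactors = FALSE)
  }))
}

spot_meta <- function(n, sample_id = "s1", group = "old") {
  data.frame(obs_id = sprintf("%s_sp%03d", sample_id, seq_len(n)),
             sample_id = sample_id, group = group, stringsAsFactors = FALSE)
}

test_that("layer profiles aggregate density and proportion correctly", {
  meta <- spot_meta(90)
  zn <- make_layers(meta)
  ab <- cbind(A = rep(2, 90), B = seq(0.1, 9, length.out = 90))
  rownames(ab) <- meta$obs_id
  pr <- layer_profile(ab, zn, meta)
  a <- pr[pr$cell_type == "A", ]
  expect_equal(a$mean_density, rep(2, 9))
  expect_equal(a$scaled_density, rep(0, 9))  # sd = 0 guarded to 0
  # proportions: per spot A/(A+B), means bounded in (0, 1)
  expect_true(all(pr$mean_proportion > 0 & pr$mean_proportion < 1))
  # a type present only in the top layer of one sample holds the max scaled value
  ab2 <- cbind(ab, C = c(rep(0, 80), rep(5, 10)))
  pr2 <- layer_profile(ab2, zn, meta)
  cc <- pr2[pr2$cell_type == "C", ]
  expect_equal(cc$layer[which.max(cc$scaled_density)], 9L)
  # spots without a layer are an error
  expect_error(layer_profile(ab, zn[-1, ], meta), "no layer")
})

test_that("rows with zero total density yield all-zero proportions", {
  ab <- matrix(c(0, 0, 1, 3), 2, 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("A", "B")))
  pr <- abundance_proportions(ab)
  expect_equal(unname(pr["a", ]), c(0, 0))
  expect_equal(sum(pr["b", ]), 1)
})

test_that("density correlation recovers perfect and inverted profiles", {
  meta <- spot_meta(90)
  zn <- make_layers(meta)
  set.seed(5)
  base <- runif(90, 1, 3)
  ab <- cbind(focal = base, same = base, anti = max(base) + min(base) - base,
              flat = rep(1, 90))
  rownames(ab) <- meta$obs_id
  pr <- layer_profile(ab, zn, meta)
  res <- density_correlation(pr, focal = "focal")
  expect_equal(res$r[res$other == "same"], 1, tolerance = 1e-12)
  expect_equal(res$r[res$other == "anti"], -1, tolerance = 1e-12)
  expect_true(is.na(res$r[res$other == "flat"]))
  expect_match(res$note[res$other == "flat"], "zero variance")
  expect_true(all(res$n_points == 9))
})

test_that("score correlations are exact for affine-related signatures", {
  set.seed(6)
  s <- matrix(rnorm(50), 50, 1, dimnames = list(sprintf("sp%02d", 1:50), "a"))
  scores <- cbind(s, b = 3 * s[, 1] + 2, c = rnorm(50))
  colnames(scores) <- c("a", "b", "c")
  res <- score_correlation(scores, "a", "a")
  expect_equal(res$r, 1, tolerance = 1e-12)
  res_affine <- score_correlation(scores, "a", "b")
  expect_equal(res_affine$r, 1, tolerance = 1e-12)
  expect_error(score_correlation(scores[1:2, , drop = FALSE], "a", "b"), "3 spots")
})

test_that("permutation colocalization: maximal statistic and add-one p", {
  meta <- spot_meta(60)
  set.seed(7)
  ab <- cbind(A = runif(60), B = 0)
  ab[, "B"] <- ab[, "A"]
  rownames(ab) <- meta$obs_id
  res <- permutation_coloc(ab, meta, "A", "B", n_perm = 199, seed = 3)
  expect_equal(res$observed, 1)
  expect_equal(res$p_perm, 1 / 200)
  expect_gt(res$p_perm, 0)  # add-one rule: never exactly 0
})

test_that("permutation colocalization is scale invariant and seeded", {
  meta <- rbind(spot_meta(40, "s1"), spot_meta(40, "s2"))
  set.seed(8)
  ab <- cbind(A = runif(80), B = runif(80))
  rownames(ab) <- meta$obs_id
  r1 <- permutation_coloc(ab, meta, "A", "B", n_perm = 99, seed = 5)
  ab2 <- ab
  ab2[, "B"] <- ab2[, "B"] * 2
  r2 <- permutation_coloc(ab2, meta, "A", "B", n_perm = 99, seed = 5)
  expect_equal(r2$observed, r1$observed, tolerance = 1e-12)
  expect_identical(r2$p_perm, r1$p_perm)
  r3 <- permutation_coloc(ab, meta, "A", "B", n_perm = 99, seed = 5)
  expect_identical(r1$p_perm, r3$p_perm)
  expect_identical(r1$null, r3$null)
})

test_that("degenerate samples are excluded with a warning", {
  meta <- rbind(spot_meta(30, "ok"), spot_meta(2, "tiny"))
  set.seed(9)
  ab <- cbind(A = runif(32), B = runif(32))
  rownames(ab) <- meta$obs_id
  expect_warning(res <- permutation_coloc(ab, meta, "A", "B", n_perm = 49, seed = 1),
                 "tiny")
  expect_identical(res$excluded_samples, "tiny")
})

test_that("observed statistic equals the spot-level Pearson r in one sample", {
  # with one spot per layer, the layer profile is the spot-level density,
  # so density_correlation and the permutation observed statistic coincide
  meta <- spot_meta(9)
  zn <- make_layers(meta, n_layers = 9)
  set.seed(10)
  ab <- cbind(A = runif(9), B = runif(9))
  rownames(ab) <- meta$obs_id
  pr <- layer_profile(ab, zn, meta)
  r_layer <- density_correlation(pr, "A", "B")$r
  res <- permutation_coloc(ab, meta, "A", "B", n_perm = 19, seed = 2)
  expect_equal(res$observed, r_layer, tolerance = 1e-12)
  expect_equal(res$observed, cor(ab[, "A"], ab[, "B"]), tolerance = 1e-12)
})

test_that("the min_product statistic is available and bounded", {
  meta <- spot_meta(50)
  set.seed(11)
  ab <- cbind(A = runif(50), B = runif(50))
  rownames(ab) <- meta$obs_id
  res <- permutation_coloc(ab, meta, "A", "B", n_perm = 99, seed = 4,
                           stat = "min_product")
  expect_true(res$observed > 0 && res$observed <= 1)
  expect_identical(res$stat, "min_product")
})
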