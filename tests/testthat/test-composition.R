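test_that("proportions sum to one per unit and include absent types as zero", {
  meta <- block_meta(c(3, 1), c("A", "B"))
  prop <- cell_proportions(meta, by = "sample")
  expect_equal(prop$proportion[prop$cell_type == "A"], 0.75)
  expect_equal(prop$proportion[prop$cell_type == "B"], 0.25)

  meta2 <- rbind(block_meta(c(2, 2), c("A", "B"), sample_id = "s1"),
                 within(block_meta(c(4), "A", sample_id = "s2"),
                        obs_id <- paste0("x", obs_id)))
  prop2 <- cell_proportions(meta2, by = "sample")
  expect_equal(prop2$proportion[prop2$sample_id == "s2" & prop2$cell_type == "B"], 0)
  sums <- tapply(prop2$proportion, prop2$sample_id, sum)
  expect_equal(as.vector(sums), c(1, 1), tolerance = 1e-12)
})

test_that("proportion log2 fold-change uses sample-level group means", {
  meta <- rbind(
    within(block_meta(c(20, 80), c("A", "B"), group = "old", sample_id = "o1"),
           obs_id <- paste0("o1", obs_id)),
    within(block_meta(c(20, 80), c("A", "B"), group = "old", sample_id = "o2"),
           obs_id <- paste0("o2", obs_id)),
    within(block_meta(c(5, 95), c("A", "B"), group = "young", sample_id = "y1"),
           obs_id <- paste0("y1", obs_id)),
    within(block_meta(c(5, 95), c("A", "B"), group = "young", sample_id = "y2"),
           obs_id <- paste0("y2", obs_id)))
  fc <- log2fc_proportion(meta, pseudo = 0)
  expect_equal(fc$log2fc[fc$cell_type == "A"], 2)  # 0.20 vs 0.05
  expect_equal(fc$log2fc[fc$cell_type == "B"], log2(0.8 / 0.95))
  expect_true(all(diff(fc$log2fc) <= 0))  # sorted decreasing
  # pseudocount keeps a type absent from one group finite
  meta_abs <- meta
  meta_abs$cell_type[meta_abs$group == "young" & meta_abs$cell_type == "A"] <- "B"
  fc2 <- log2fc_proportion(meta_abs, pseudo = 1e-4)
  expect_true(is.finite(fc2$log2fc[fc2$cell_type == "A"]))
  expect_gt(fc2$log2fc[fc2$cell_type == "A"], 0)
})

test_that("Ro/e and chi-square match the worked 2x2 example", {
  meta <- rbind(
    within(block_meta(c(30, 70), c("X", "other"), group = "old"),
           obs_id <- paste0("o", obs_id)),
    within(block_meta(c(10, 90), c("X", "other"), group = "young"),
           obs_id <- paste0("y", obs_id)))
  res <- roe_enrichment(meta, universe = c("X", "other"))
  x <- res[res$cell_type == "X", ]
  expect_equal(x$expected_old, 20)
  expect_equal(x$roe, 1.5)
  expect_equal(x$chi2, 12.5)
  expect_equal(x$p, pchisq(12.5, 1, lower.tail = FALSE))
  expect_equal(x$p, 4.07e-4, tolerance = 1e-2)
})

test_that("an exactly independent table gives Ro/e 1 and chi2 0", {
  meta <- rbind(
    within(block_meta(c(20, 80), c("X", "other"), group = "old"),
           obs_id <- paste0("o", obs_id)),
    within(block_meta(c(10, 40), c("X", "other"), group = "young"),
           obs_id <- paste0("y", obs_id)))
  res <- roe_enrichment(meta, universe = c("X", "other"))
  expect_equal(res$roe, c(1, 1))
  expect_equal(res$chi2, c(0, 0), tolerance = 1e-12)
  expect_equal(res$p, c(1, 1))
})

test_that("swapping group labels preserves chi2 and p", {
  set.seed(12)
  meta <- rbind(
    within(block_meta(c(33, 67), c("X", "other"), group = "old"),
           obs_id <- paste0("o", obs_id)),
    within(block_meta(c(41, 29), c("X", "other"), group = "young"),
           obs_id <- paste0("y", obs_id)))
  res <- roe_enrichment(meta, universe = c("X", "other"))
  swapped <- meta
  swapped$group <- ifelse(meta$group == "old", "young", "old")
  res_sw <- roe_enrichment(swapped, universe = c("X", "other"))
  expect_equal(res_sw$chi2, res$chi2, tolerance = 1e-12)
  expect_equal(res_sw$p, res$p, tolerance = 1e-12)
})

test_that("chi2 agrees with the brute-force oracle on random tables", {
  set.seed(99)
  for (i in 1:50) {
    counts <- rmultinom(1, 40 + rpois(1, 200), runif(4, 0.05, 1))
    meta <- rbind(
      within(block_meta(counts[1:2], c("X", "other"), group = "old"),
             obs_id <- paste0("o", obs_id)),
      within(block_meta(counts[3:4], c("X", "other"), group = "young"),
             obs_id <- paste0("y", obs_id)))
    res <- roe_enrichment(meta, universe = c("X", "other"))
    tab <- matrix(counts, 2, 2)  # rows X/other, cols old/young
    expect_equal(res$chi2[res$cell_type == "X"], chi2_oracle(tab),
                 tolerance = 1e-12)
    expect_equal(res$roe[res$cell_type == "X"],
                 tab[1, 1] / (sum(tab[, 1]) * sum(tab[1, ]) / sum(tab)),
                 tolerance = 1e-15)
  }
})

test_that("the universe is explicit and small expected counts are flagged", {
  meta <- rbind(
    within(block_meta(c(100), "other", group = "old"),
           obs_id <- paste0("o", obs_id)),
    within(block_meta(c(1, 300), c("rare", "other"), group = "young"),
           obs_id <- paste0("y", obs_id)))
  expect_error(roe_enrichment(meta), "universe")
  res <- roe_enrichment(meta, universe = unique(meta$cell_type))
  expect_false(res$reliable[res$cell_type == "rare"])
  expect_true(all(is.finite(res$p)))
  expect_true(all(res$p_adj >= res$p))
})
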