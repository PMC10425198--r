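viz_fixture <- function() {
  m <- matrix(c(10, 12, 30, 28,
                40, 38, 10, 12,
                25, 25, 30, 30), nrow = 3, byrow = TRUE)
  feats <- c("ko00010", "ko00020", "ko00030")
  dimnames(m) <- list(feats, paste0("S", 1:4))
  tab <- as_abundance(dplyr::bind_cols(tibble::tibble(feature = feats),
                                       tibble::as_tibble(m, .name_repair = "minimal")),
                      "KEGG_PATHWAY")
  meta <- tiny_metadata(samples = paste0("S", 1:4))
  res <- tibble::tibble(feature = feats, method = "welch_t", group1 = "A",
                        group2 = "B", effect = c(1.4, -1.9, 0.1),
                        p_value = c(0.001, 0.002, 0.8),
                        p_adjust = c(0.003, 0.006, 0.9), adjust_method = "BH")
  list(tab = tab, meta = meta, res = res, m = m)
}

test_that("errorbar layer reports hand-computed TSS means and SEMs", {
  fx <- viz_fixture()
  eb <- pathway_errorbar(fx$tab, fx$meta, fx$res, threshold = 0.05)
  lay <- tidy(eb)
  expect_setequal(unique(lay$feature), c("ko00010", "ko00020"))
  rel <- sweep(fx$m, 2, colSums(fx$m), "/")
  want_mean <- mean(rel["ko00010", c("S1", "S2")])
  got <- lay[lay$feature == "ko00010" & lay$group == "A", ]
  expect_equal(got$mean_rel_abundance, want_mean)
  expect_equal(got$sem, sd(rel["ko00010", c("S1", "S2")]) / sqrt(2))
  # ordered by adjusted p, ties by feature id
  expect_equal(unique(lay$feature[order(lay$order)]), c("ko00010", "ko00020"))
})

test_that("errorbar filtering contracts: threshold, select and the display cap", {
  fx <- viz_fixture()
  all_in <- pathway_errorbar(fx$tab, fx$meta, fx$res, threshold = 1.0)
  expect_equal(length(unique(tidy(all_in)$feature)), 3)
  sel <- pathway_errorbar(fx$tab, fx$meta, fx$res, threshold = 0.05,
                          select = "ko00020")
  expect_identical(unique(tidy(sel)$feature), "ko00020")
  expect_error(pathway_errorbar(fx$tab, fx$meta, fx$res, threshold = 1e-9),
               "no feature passes")

  # 31 significant features trip the cap and the message names the remedy
  set.seed(19)
  big <- random_abundance(31, 4)
  meta <- tiny_metadata(samples = names(big)[-1])
  res31 <- tibble::tibble(feature = big$feature, method = "welch_t",
                          group1 = "A", group2 = "B", effect = 1,
                          p_value = 0.001, p_adjust = 0.01, adjust_method = "BH")
  expect_error(pathway_errorbar(big, meta, res31), "31.*30.*select")
})

test_that("viz layers are pure functions of their inputs", {
  fx <- viz_fixture()
  l1 <- tidy(pathway_errorbar(fx$tab, fx$meta, fx$res))
  l2 <- tidy(pathway_errorbar(fx$tab, fx$meta, fx$res))
  expect_identical(l1, l2)
  p1 <- pathway_pca(fx$tab, fx$meta, k = 2)
  p2 <- pathway_pca(fx$tab, fx$meta, k = 2)
  expect_identical(p1$layer, p2$layer)
  expect_identical(p1$variance_fraction, p2$variance_fraction)
  h1 <- tidy(pathway_heatmap(fx$tab, fx$meta))
  expect_identical(h1, tidy(pathway_heatmap(fx$tab, fx$meta)))
})

test_that("PCA variance fractions follow rank and duplication identities", {
  fx <- viz_fixture()
  pc <- pathway_pca(fx$tab, fx$meta, k = 2)
  expect_true(all(diff(pc$variance_fraction) <= 1e-9))      # non-increasing
  expect_lte(sum(pc$variance_fraction), 1 + 1e-9)

  # two distinct samples: a single nonzero variance fraction equal to 1
  two <- fx$tab[, c("feature", "S1", "S3")]
  meta2 <- tiny_metadata(samples = c("S1", "S3"), groups = c("A", "B"))
  pc2 <- pathway_pca(as_abundance(two, "KEGG_PATHWAY"), meta2, k = 1)
  expect_equal(pc2$variance_fraction[1], 1)
  expect_error(pathway_pca(as_abundance(two, "KEGG_PATHWAY"), meta2, k = 2),
               "rank")

  # duplicating every sample leaves the spectrum unchanged
  dup <- fx$tab
  dupm <- cbind(fx$m, fx$m)
  colnames(dupm) <- paste0("S", 1:8)
  dup_tab <- as_abundance(dplyr::bind_cols(tibble::tibble(feature = fx$tab$feature),
                                           tibble::as_tibble(dupm, .name_repair = "minimal")),
                          "KEGG_PATHWAY")
  meta8 <- tiny_metadata(samples = paste0("S", 1:8),
                         groups = rep(c("A", "A", "B", "B"), 2))
  pc_dup <- pathway_pca(dup_tab, meta8, k = 2)
  nz <- pc$variance_fraction[pc$variance_fraction > 1e-12]
  nz_dup <- pc_dup$variance_fraction[pc_dup$variance_fraction > 1e-12]
  expect_equal(nz_dup, nz, tolerance = 1e-9)
})

test_that("heatmap rows are z-scored with the sample standard deviation", {
  m <- matrix(c(1, 2, 3, 5, 5, 5), nrow = 2, byrow = TRUE)
  feats <- c("f1", "f2")
  dimnames(m) <- list(feats, c("S1", "S2", "S3"))
  tab <- as_abundance(dplyr::bind_cols(tibble::tibble(feature = feats),
                                       tibble::as_tibble(m, .name_repair = "minimal")))
  meta <- tiny_metadata(samples = c("S1", "S2", "S3"), groups = c("A", "B", "B"))
  expect_warning(hm <- pathway_heatmap(tab, meta), "constant")
  lay <- tidy(hm)
  expect_equal(lay$z[lay$feature == "f1"], c(-1, 0, 1))
  expect_equal(lay$z[lay$feature == "f2"], c(0, 0, 0))
})

test_that("heatmap columns are ordered by group then sample id", {
  fx <- viz_fixture()
  meta <- tiny_metadata(samples = paste0("S", 1:4), groups = c("B", "A", "B", "A"))
  hm <- pathway_heatmap(fx$tab, meta)
  expect_identical(hm$col_order, c("S2", "S4", "S1", "S3"))
  expect_error(pathway_heatmap(fx$tab, meta, features = character()), "empty")
  expect_error(pathway_heatmap(fx$tab, meta, features = "nope"), "not in table")
})

test_that("figures render from precomputed layers without altering them", {
  fx <- viz_fixture()
  eb <- pathway_errorbar(fx$tab, fx$meta, fx$res)
  before <- tidy(eb)
  dir <- withr::local_tempdir()
  paths <- write_figure(eb, file.path(dir, "eb"), formats = "png")
  expect_true(file.exists(paths[1]))
  expect_identical(tidy(eb), before)
  expect_s3_class(autoplot(pathway_pca(fx$tab, fx$meta)), "ggplot")
  expect_s3_class(autoplot(suppressWarnings(pathway_heatmap(fx$tab, fx$meta))), "ggplot")
})
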